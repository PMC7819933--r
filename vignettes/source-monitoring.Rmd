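---
title: "Measuring source memory with the two-high-threshold multinomial model"
author: "sourcemem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring source memory with the two-high-threshold multinomial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcemem)
```

## The measurement problem

In a source-monitoring test, participants see old items (words, faces)
that were studied in one of two contexts ("sources") together with new
items, and must answer "Source A", "Source B" or "new".  The observed
response proportions confound three different processes: recognizing the
item at all (*item memory*), remembering its context (*source memory*),
and systematic guessing.  A participant with no source memory but a
strong bias to attribute, say, kitchen-typical objects to the kitchen can
look deceptively accurate on schema-consistent pairs.  Any claim about
memory for *expected* versus *unexpected* item-source pairings therefore
needs a measurement model that separates memory from guessing.

`sourcemem` implements the standard two-high-threshold source-monitoring
(2HTSM) multinomial processing tree for this purpose, together with the
full inferential toolchain around it: joint maximum-likelihood fitting
over several conditions with equality constraints, likelihood-ratio
(G²) model comparisons with Cohen's *w*, Wald confidence intervals,
noncentral-χ² sensitivity power analysis, and contrast-score ANOVAs for
the 0–100 metamemory judgment scales that typically accompany such
experiments.  A seeded generator produces complete synthetic experiments
so that every stage can be exercised and validated without any external
data.

## The model

Each experimental condition (one *tree set*) has three trees, one per
item class shown at test.  The parameters are probabilities:

* `D` — detecting an old item as old, and a new item as new.  The single
  `D` per tree set encodes the usual identifiability restriction
  `D_A = D_B = D_New`; without it the model has more parameters than a
  3×3 table has free categories.
* `d_A`, `d_B` — conditionally on detection, remembering that the item
  came from Source A (resp. B).
* `b` — guessing "old" for an undetected item.
* `g` — guessing Source A when no source information is available.

Reading the branches off the trees gives, for Source-A items,

$$P(\text{"A"}\mid A) = D d_A + D(1-d_A)g + (1-D)bg,$$
$$P(\text{"B"}\mid A) = D(1-d_A)(1-g) + (1-D)b(1-g),$$
$$P(\text{"new"}\mid A) = (1-D)(1-b),$$

with the symmetric expressions (swap `d_A` for `d_B` and `g` for `1-g`)
for Source-B items, and for new items

$$P(\text{"A"}\mid \text{new}) = (1-D)bg,\qquad
  P(\text{"new"}\mid \text{new}) = D + (1-D)(1-b).$$

`category_probabilities()` evaluates these exactly; the test suite checks
them against an independent enumeration of the latent memory states and
verifies the label-swap symmetry (A↔B, `g`↔`1-g`).  The equations agree
with the standard 2HTSM submodel that uses one detection parameter per
tree set; we derived them from the trees' verbal description and flag
that any divergence from other software's conventions should be reported
rather than silently absorbed.

A deliberate narrowing: the unrestricted variant with three separate
detection parameters per tree set is *not* constructible here, because no
supported analysis uses it and it is not identified from a single 3×3
table.

## Estimation

`fit_mpt()` maximizes the joint multinomial log-likelihood of one 3×3
frequency table per tree set.  A `model_spec()` maps every
(condition, parameter) cell to a symbol; `equate()` merges symbols
(equality constraints across conditions) and `fix_par()` pins them to
constants.  Degrees of freedom follow the usual bookkeeping: six free
categories per tree set minus the number of free symbols — for four tree
sets and the 20-symbol base model, df = 4.

Numerical choices, in order of consequence:

* Optimization runs on the logit scale (estimates cannot leave the unit
  interval) with BFGS and an analytic gradient; the cell probabilities
  are multilinear in the parameters, so the gradient is exact and cheap.
* The first start is a method-of-moments inversion of the hit,
  false-alarm and source-attribution rates, averaged over the conditions
  tied to each symbol; by default ten seeded random restarts follow.
  Ties among restart winners break by highest log-likelihood, then lowest
  restart index, making fits bit-reproducible given (data, spec, seed).
  The simulation suites use fewer restarts: with the moment start the
  joint likelihood has shown no multimodality in any of our checks, and
  the restart count is a pure runtime multiplier there.
* Convergence tolerance is `reltol = 1e-12` on the log-likelihood.
* `0·log 0 := 0` throughout; a positive count on a zero-probability cell
  yields `-Inf` log-likelihood and an infinite G² flag rather than an
  error.
* Parameters are clamped to `[1e-10, 1 - 1e-10]` inside the objective so
  that boundary iterates cannot produce exact zero probabilities by
  rounding.

G² is computed as twice the gap to the saturated model, with
`p = chi2_sf(G2, df)` and Cohen's `w = sqrt(G2 / N)`, where `N` is the
total number of test responses (participants × test trials) — the
convention that reproduces published (ΔG², w) pairs.

Confidence intervals are Wald intervals on the probability scale, from
the inverse observed information over the free symbols, clipped to
`[0, 1]`.  This is an assumption, not a mathematical necessity — other
software may profile or transform — and it has a known consequence that
we document rather than hide: when a *correlated* parameter sits close to
the boundary (for example a source-memory parameter near 0.1), the
intervals for the guessing parameters become conservative; at one such
configuration we measured ≈98.5% coverage for a nominal 95% interval.
At interior configurations (all parameters roughly in 0.25–0.75) measured
coverage is 0.94–0.96 for every symbol.  Estimates at the boundary are
flagged and get one-sided intervals; a singular information matrix is
flagged and yields maximally wide clipped intervals.

## The analysis plan for a 2 × 2 design

`source_memory_analysis()` runs the canonical sequence for experiments
crossing an item/face type with a judgment group:

1. **Base model** (df 4): one `D` per tree set, everything else free.
2. **Item memory by type** (Δdf 2) and **by group** (Δdf 2), each tested
   against the base model.  The Results-style ordering tests these
   against the *first* base model rather than the later reference model;
   this matches the narrative order of such analyses and is flagged here
   because the alternative is defensible too.
3. **Expectancy-equated reference model** (df 8): within each group one
   shared source-memory parameter for schema-*expected* pairings and one
   for *unexpected* pairings.  The expected cell mapping is fixed by the
   design: with Source A = kitchen, the expected parameter is `d_A` for
   kitchen-typical items and `d_B` for bathroom-typical items; with
   Source A = cheating, it is `d_A` for untrustworthy-looking faces and
   `d_B` for trustworthy-looking ones.
4. **Expectancy-violation tests** (Δdf 1 per group):
   `d_expected = d_unexpected` within each group.
5. **Source memory by group** (Δdf 2) and **guessing bias per group**
   (Δdf 1 each), against the reference model.

ΔG² differences that come out slightly negative (within `1e-4`) are
clipped to zero with a warning — a finite-tolerance optimizer artifact —
and anything more negative raises an error, because it indicates
non-nested specs.  The significance level is .05 throughout; the
Bonferroni-corrected .025 applies only to the ANOVA simple-effect
follow-ups, not to the model comparisons.

## Sensitivity power analysis

`sensitivity_w()` answers "what is the smallest Cohen's *w* this design
can detect": it solves for the noncentrality λ\* at which the
noncentral-χ² survival function at the central critical value reaches the
requested power, by bisection (the function is monotone in λ, so the
root is unique; tolerance `1e-8`), and returns
`w = sqrt(λ*/N)`.  The df of the intended test changes the answer
noticeably, and published sensitivity statements often omit it —
the two study-sized examples bundled in the tests are mutually
inconsistent under any single df — so `sensitivity_sweep()` reports the
whole df profile instead of asserting a match at one df.

## Judgment ANOVAs

Every factor in these designs has exactly two levels, so each
within-subject effect is a single-degree-of-freedom contrast of the four
cell means.  `rm_anova_2x2()` and `mixed_anova_2x2x2()` therefore compute
each F as a squared t of per-participant contrast scores: transparent,
exactly equal to the classical repeated-measures/mixed decomposition for
2-level factors (the suite verifies the equality against `aov()` on a
balanced design), and trivially testable.  For mixed designs the within
main effects use the unweighted mean of group means over pooled variance
(Type-III behavior under unbalance), interactions with group are
two-sample comparisons of contrast scores, and all group-involving tests
have `df2 = n1 + n2 - 2`.  Partial eta squared is `F·df1/(F·df1 + df2)`.
Participants with any missing cell are listwise-excluded and counted
(`n_excluded` attribute).  Zero contrast variance yields F = 0 when the
contrast is identically zero and a flagged `NA` otherwise.  Simple
interaction effects per group run at α/2 = .025 when the Bonferroni flag
is on (the default).

## The synthetic data generator

`simulate_experiment()` emulates two designs end to end, plus a
belief-survey variant:

* **Rooms × objects**: two judgment groups of 60, 96 objects in three
  counterbalanced lists of 32 (16 bathroom-typical + 16 kitchen-typical
  each).  Per participant one list is studied with the kitchen source and
  one with the bathroom source — 32 expected and 32 unexpected pairs —
  and one serves as distractors, giving 96 test trials; list roles rotate
  across consecutive participants so that each list appears equally often
  in each role.  Two buffer study trials are emitted but flagged and
  excluded from aggregation.
* **Faces × cheating/cooperation**: groups of 93 and 92, 40 game partners
  (10 per trustworthiness × behavior cell) plus 40 new faces at test; two
  practice rounds flagged as buffers.  Game investment (15/30 cents),
  payoff (±5/±10) and test-phase likability columns are emitted for
  schema fidelity; their inferential analysis is out of scope.
* **Belief survey**: 100 respondents rating the four trustworthiness ×
  behavior cells without having experienced the game.

Test responses are drawn per trial from `category_probabilities()` of the
condition's parameter vector.  Judgments follow an additive Gaussian
model on the 0–100 scale — grand mean + expectancy effect + participant
intercept + residual, clipped to the scale — with *participant-level
random slopes* for the expectancy effect: participants differ in how
strongly they show the illusion, which is what keeps simulated effect
sizes in a realistic range rather than near 1.

Because the study's cell means and parameter estimates exist only in
figures, all generator defaults are synthetic.  Their *magnitudes* are
calibrated once against the published test statistics, which are exact
inputs: the default source-memory gaps and detection differences imply
likelihood-ratio noncentralities close to the published ΔG² values at the
default design sizes (e.g. λ ≈ 2.9 and ≈ 124 for the two headline tests
of the rooms design; λ ≈ 8.2 and ≈ 55 for the faces design), and the
judgment slope SDs imply partial eta squared near the published values
(≈ 0.54/0.31 for the rooms design judgments, ≈ 0.22 for faces).  The
individual probabilities and scale means remain invented.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real stimulus content and item-level
difficulty, sequential and fatigue effects, between-participant
heterogeneity in the *model* parameters (each condition is one
homogeneous multinomial; real data are overdispersed relative to this),
response times, and any dependence of guessing on judgments.  Aggregated
frequency tables from this generator are exactly multinomial, which is
the regime in which the χ² reference distributions are exact
asymptotically; the calibration checks below therefore validate the
machinery, not the behavior of human data.

`corrected_item_recognition()` computes the standard hit-rate minus
false-alarm-rate index per participant and item type; under the
two-high-threshold model its expected value is `D` (hits
`= D + (1-D)b`, false alarms `= (1-D)b`), which ties the trial-level
generator to the model's closed form in the suite.

## Validation summary

The package's own simulation suites (all seeded, all in the tests)
check:

* estimates at exact expected counts recover the generating parameters
  to `1e-4` with G² ≈ 0;
* the fitted likelihood dominates an exhaustive 0.02-resolution grid over
  all five parameters (the grid maximization exploits that `d_A` and
  `d_B` enter only their own rows, making the 51⁵ grid exactly
  maximizable in 51³·2·51 work);
* Wald standard errors match a Richardson-extrapolated numerical Hessian
  to better than `1e-3`;
* at the faces-design scale, 600 replicates give maximum absolute bias
  ≈ 0.011 and per-symbol CI coverage 0.94–0.96 (replicates above the
  minimum 200 because the per-symbol bias estimate at 200 replicates is
  dominated by Monte-Carlo noise of ≈ 0.008);
* with no expectancy-violation effect planted, the Δdf = 1
  likelihood-ratio test rejects at 5.2% (1500 replicates; the bundled
  acceptance run uses 600), and the ANOVA type-I error is nominal over
  2000 replicates;
* the analytic layer reproduces every published p, w and η²_p from the
  printed (statistic, df, N) inputs at printed precision — with the
  caveat that statistics printed to two decimals propagate up to ≈ 0.002
  of rounding slack into a three-decimal p.

## Known limitations

* Wald intervals on the probability scale are conservative for parameters
  correlated with near-boundary parameters (measured up to ≈ 98.5%
  coverage); profile-likelihood or bootstrap intervals would fix this and
  are natural extensions, as is hierarchical (latent-trait) MPT
  estimation for participant heterogeneity.
* No sphericity corrections in the ANOVAs — irrelevant for 2-level
  factors, wrong for anything larger; the functions deliberately refuse
  designs that are not 2 × 2 (× 2).
* The G²-based comparisons assume the multinomial sampling scheme;
  overdispersed real data make the tests anticonservative.
* Model selection beyond nested G² tests (AIC/BIC, ROC-based alternative
  measurement models) is intentionally out of scope.
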