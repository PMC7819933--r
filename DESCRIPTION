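Package: sourcemem
Title: Two-High-Threshold Source-Monitoring Models and Metamemory Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring source memory, item memory and guessing with
    the two-high-threshold source-monitoring multinomial processing tree
    model.  Provides exact category probabilities for the model trees, joint
    maximum likelihood estimation across several tree sets under equality
    constraints, likelihood-ratio (G-squared) goodness-of-fit and nested
    model comparisons with Cohen's w effect sizes and Wald confidence
    intervals, sensitivity power analysis for chi-square tests via the
    noncentral chi-square distribution, contrast-score repeated-measures and
    mixed ANOVAs with partial eta squared for 0-100 metamemory judgment
    scales, and a seeded generator of synthetic source-monitoring experiments
    (expected versus unexpected item-source pairings, with and without
    judgments of learning) so that every analysis stage runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
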