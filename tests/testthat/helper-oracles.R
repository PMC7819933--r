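# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package (latent-state
# enumeration, cell-by-cell loops, exhaustive grid maximization,
# Monte-Carlo sampling) so that agreement is evidence, not tautology.

# Category probabilities by enumeration of the latent memory states of the
# two-high-threshold trees: detect -> (source memory | guess source) for
# old items, detect -> "new" for new items, guess-old -> guess source
# otherwise.  Returns the same 3x3 layout as category_probabilities().
oracle_category_probs <- function(D, d_A, d_B, b, g) {
  acc <- matrix(0, 3, 3,
                dimnames = list(c("sourceA_old", "sourceB_old", "new"),
                                c("respA", "respB", "respNew")))
  add <- function(row, resp, pr) acc[row, resp] <<- acc[row, resp] + pr
  for (detect in 0:1) {
    p_det <- if (detect) D else 1 - D
    # old items, source A and B
    for (src in c("sourceA_old", "sourceB_old")) {
      d_src <- if (src == "sourceA_old") d_A else d_B
      correct <- if (src == "sourceA_old") "respA" else "respB"
      if (detect) {
        for (src_mem in 0:1) {
          p_sm <- if (src_mem) d_src else 1 - d_src
          if (src_mem) {
            add(src, correct, p_det * p_sm)
          } else {
            for (guessA in 0:1) {
              p_g <- if (guessA) g else 1 - g
              add(src, if (guessA) "respA" else "respB",
                  p_det * p_sm * p_g)
            }
          }
        }
      } else {
        for (guess_old in 0:1) {
          p_b <- if (guess_old) b else 1 - b
          if (guess_old) {
            for (guessA in 0:1) {
              p_g <- if (guessA) g else 1 - g
              add(src, if (guessA) "respA" else "respB",
                  p_det * p_b * p_g)
            }
          } else {
            add(src, "respNew", p_det * p_b)
          }
        }
      }
    }
    # new items: detection means correctly calling the item new
    if (detect) {
      add("new", "respNew", p_det)
    } else {
      for (guess_old in 0:1) {
        p_b <- if (guess_old) b else 1 - b
        if (guess_old) {
          for (guessA in 0:1) {
            p_g <- if (guessA) g else 1 - g
            add("new", if (guessA) "respA" else "respB",
                p_det * p_b * p_g)
          }
        } else {
          add("new", "respNew", p_det * p_b)
        }
      }
    }
  }
  acc
}

# Cell-by-cell log-likelihood summation.
oracle_loglik <- function(counts, probs) {
  ll <- 0
  for (i in 1:3) for (j in 1:3) {
    n <- counts[i, j]
    if (n > 0) {
      if (probs[i, j] == 0) return(-Inf)
      ll <- ll + n * log(probs[i, j])
    }
  }
  ll
}

# Exhaustive maximization of the single-tree-set log-likelihood on a
# regular grid.  Exploits that, given (D, b, g), the source-memory
# parameters d_A and d_B each enter only their own row, so the inner
# maximizations are independent; the result is the exact maximum over the
# full 5-dimensional grid.
oracle_grid_max_loglik <- function(counts, step = 0.02) {
  grid1 <- seq(0, 1, by = step)
  gr <- expand.grid(D = grid1, b = grid1, g = grid1)
  D <- gr$D; b <- gr$b; g <- gr$g
  n <- unclass(counts)
  safelog <- function(p) log(pmax(p, 1e-300))
  zero_ok <- function(p, cnt) ifelse(p == 0 & cnt > 0, -Inf, cnt * safelog(p))

  # rows share probability (1-D)(1-b) for "resp new"
  pN_old <- (1 - D) * (1 - b)
  best_A <- rep(-Inf, nrow(gr))
  best_B <- rep(-Inf, nrow(gr))
  for (d in grid1) {
    pA <- D * d + D * (1 - d) * g + (1 - D) * b * g
    pB <- D * (1 - d) * (1 - g) + (1 - D) * b * (1 - g)
    llA <- zero_ok(pA, n[1, 1]) + zero_ok(pB, n[1, 2]) +
      zero_ok(pN_old, n[1, 3])
    best_A <- pmax(best_A, llA)
    pA2 <- D * (1 - d) * g + (1 - D) * b * g
    pB2 <- D * d + D * (1 - d) * (1 - g) + (1 - D) * b * (1 - g)
    llB <- zero_ok(pA2, n[2, 1]) + zero_ok(pB2, n[2, 2]) +
      zero_ok(pN_old, n[2, 3])
    best_B <- pmax(best_B, llB)
  }
  ll_new <- zero_ok((1 - D) * b * g, n[3, 1]) +
    zero_ok((1 - D) * b * (1 - g), n[3, 2]) +
    zero_ok(D + (1 - D) * (1 - b), n[3, 3])
  max(best_A + best_B + ll_new)
}

# Expected counts at a parameter vector (exact integers when the category
# probabilities have at most three decimals and n is a multiple of 1000).
expected_counts <- function(theta, n_per_row) {
  p <- category_probabilities(theta)
  frequency_table(round(p * n_per_row))
}

# Random interior parameter vector.
random_theta <- function(lo = 0, hi = 1) {
  v <- runif(5, lo, hi)
  htsm_par(v[1], v[2], v[3], v[4], v[5])
}

# Reference counts used by several fitting tests (about 100 per row).
grid_example_counts <- function() {
  frequency_table(rbind(c(60, 25, 15), c(25, 60, 15), c(20, 20, 60)),
                  label = "grid-example")
}

# Exp. 2-scale per-condition row totals (participants x trials per cell).
exp2_row_totals <- function() {
  list(without.trustworthy = c(930, 930, 1860),
       without.untrustworthy = c(930, 930, 1860),
       with.trustworthy = c(920, 920, 1840),
       with.untrustworthy = c(920, 920, 1840))
}

# Specs of the expectancy-equated reference model and its single-group
# d_expected = d_unexpected restriction, built independently of
# source_memory_analysis() plumbing for use in calibration loops.
expectancy_specs <- function(conds = names(exp2_row_totals()),
                             experiment = "exp2") {
  des <- condition_design(conds)
  des$expected_par <- ifelse(
    des$type == (if (experiment == "exp2") "untrustworthy" else "kitchen"),
    "d_A", "d_B")
  des$unexpected_par <- ifelse(des$expected_par == "d_A", "d_B", "d_A")
  spec <- model_spec(conds)
  for (gr in unique(des$group)) {
    sel <- des$group == gr
    spec <- equate(spec, paste(des$expected_par[sel], des$condition[sel],
                               sep = "."),
                   to = paste("d_expected", gr, sep = "."))
    spec <- equate(spec, paste(des$unexpected_par[sel], des$condition[sel],
                               sep = "."),
                   to = paste("d_unexpected", gr, sep = "."))
  }
  restricted <- equate(spec, c("d_expected.without", "d_unexpected.without"),
                       to = "d.without")
  list(reference = spec, restricted_without = restricted)
}
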