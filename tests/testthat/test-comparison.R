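# Nested model comparisons and the four-table analysis plan.

test_that("comparing a model with itself gives a null result", {
  tabs <- simulate_tables(default_theta("exp1"), c(100, 100, 100),
                          seed = 2)
  fit <- fit_mpt(model_spec(names(tabs)), tabs, n_restarts = 2)
  cc <- compare_models(fit, fit)
  expect_equal(cc$delta_G2, 0)
  expect_equal(cc$delta_df, 0L)
  expect_equal(cc$p_value, 1)
})

test_that("published delta-G2 test statistics reproduce their p-values", {
  expect_lt(abs(chi2_sf(3.96, 1) - 0.047), 0.0025)
  expect_lt(abs(chi2_sf(11.68, 8) - 0.166), 0.0025)
})

test_that("non-nested comparisons are rejected", {
  tabs <- simulate_tables(default_theta("exp1"), c(100, 100, 100),
                          seed = 2)
  conds <- names(tabs)
  full <- fit_mpt(equate(model_spec(conds), paste0("D.", conds[1:2]),
                         to = "Dx"), tabs, n_restarts = 2)
  other <- fit_mpt(equate(model_spec(conds), paste0("D.", conds[3:4]),
                          to = "Dy"), tabs, n_restarts = 2)
  expect_error(compare_models(other, full), "not nested")
})

test_that("a planted source-memory difference is detected with growing N", {
  theta <- default_theta("exp2")     # without group: d differs by 0.30
  specs <- expectancy_specs()
  rates <- sapply(c(60, 8000), function(n_row) {
    reject <- 0
    set.seed(31)
    for (r in 1:15) {
      tabs <- simulate_tables(theta, c(n_row, n_row, 2 * n_row))
      full <- fit_mpt(specs$reference, tabs, n_restarts = 1)
      nested <- fit_mpt(specs$restricted_without, tabs, n_restarts = 1)
      cc <- suppressWarnings(compare_models(nested, full))
      reject <- reject + (cc$p_value < 0.05)
    }
    reject / 15
  })
  expect_lte(rates[1], rates[2])
  expect_equal(rates[2], 1)          # consistency: power -> 1
})

test_that("planted-effect rejection rate matches the noncentral chi-square oracle", {
  # noncentrality from the G2 gap at exact expected proportions
  theta <- default_theta("exp2")
  n_row <- list(without.trustworthy = c(930, 930, 1860),
                without.untrustworthy = c(930, 930, 1860),
                with.trustworthy = c(920, 920, 1840),
                with.untrustworthy = c(920, 920, 1840))
  specs <- expectancy_specs()
  exact <- lapply(names(theta), function(cond) {
    frequency_table(round(category_probabilities(theta[[cond]]) *
                            n_row[[cond]]))
  })
  names(exact) <- names(theta)
  lambda <- fit_mpt(specs$restricted_without, exact, n_restarts = 1)$G2 -
    fit_mpt(specs$reference, exact, n_restarts = 1)$G2
  pow <- chi2_power(lambda, df = 1, alpha = 0.05)
  expect_gt(pow, 0.5)                # the planted effect is detectable

  set.seed(77)
  reject <- 0
  n_rep <- 60
  for (r in 1:n_rep) {
    tabs <- simulate_tables(theta, n_row)
    full <- fit_mpt(specs$reference, tabs, n_restarts = 1)
    nested <- fit_mpt(specs$restricted_without, tabs, n_restarts = 1)
    cc <- suppressWarnings(compare_models(nested, full))
    reject <- reject + (cc$p_value < 0.05)
  }
  se <- sqrt(pow * (1 - pow) / n_rep)
  expect_lt(abs(reject / n_rep - pow), 4 * se + 0.01)
})

test_that("stepwise delta-G2 values are additive along a nesting chain", {
  tabs <- simulate_tables(default_theta("exp1"), c(250, 250, 250),
                          seed = 8)
  conds <- names(tabs)
  specs <- expectancy_specs(conds, experiment = "exp1")
  base <- fit_mpt(model_spec(conds), tabs, n_restarts = 3)
  ee <- fit_mpt(specs$reference, tabs, n_restarts = 3)
  one_d <- fit_mpt(equate(specs$restricted_without,
                          c("d_expected.with", "d_unexpected.with"),
                          to = "d.with"), tabs, n_restarts = 3)
  total <- one_d$G2 - base$G2
  steps <- (ee$G2 - base$G2) + (one_d$G2 - ee$G2)
  expect_equal(total, steps, tolerance = 1e-6)
})

test_that("the analysis plan reproduces the df bookkeeping of the design", {
  tabs <- simulate_tables(default_theta("exp1"), c(120, 120, 120),
                          seed = 14)
  an <- source_memory_analysis(tabs, "exp1", n_restarts = 2)
  expect_equal(an$fit_rows$df, c(4L, 8L))
  expect_equal(an$comparisons$delta_df, c(2L, 2L, 1L, 1L, 2L, 1L, 1L))
  expect_equal(nrow(an$comparisons), 7L)
  expect_named(an$comparisons,
               c("test", "label", "delta_G2", "delta_df", "p", "w",
                 "decision"))
  # 4 tree sets x 6 free categories = 24; 20 free symbols in the base model
  expect_equal(length(an$fits$base$estimates), 20L)
  expect_equal(length(an$fits$expectancy_equated$estimates), 16L)
})

test_that("expected/unexpected cells map to the schema-consistent sources", {
  # exp1: Source A = kitchen; the expected pairing for kitchen items is
  # d_A, for bathroom items d_B.  Plant d_expected = 0.6, d_unexpected =
  # 0.2 and check the analysis estimates them under the right symbols.
  theta <- list(
    without.bathroom = htsm_par(0.6, d_A = 0.2, d_B = 0.6, b = 0.3, g = 0.5),
    without.kitchen = htsm_par(0.6, d_A = 0.6, d_B = 0.2, b = 0.3, g = 0.5),
    with.bathroom = htsm_par(0.6, d_A = 0.2, d_B = 0.6, b = 0.3, g = 0.5),
    with.kitchen = htsm_par(0.6, d_A = 0.6, d_B = 0.2, b = 0.3, g = 0.5))
  tabs <- lapply(theta, expected_counts, n_per_row = 1e5)
  an <- source_memory_analysis(tabs, "exp1", n_restarts = 1)
  est <- an$fits$expectancy_equated$estimates
  expect_equal(est[["d_expected.without"]], 0.6, tolerance = 1e-3)
  expect_equal(est[["d_unexpected.without"]], 0.2, tolerance = 1e-3)
  expect_equal(est[["d_expected.with"]], 0.6, tolerance = 1e-3)
})
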