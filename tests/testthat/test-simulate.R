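# Synthetic experiment generator: design arithmetic, counterbalancing,
# reproducibility, and the bridge to the model's frequency tables.

test_that("same seed reproduces the data, different seeds differ", {
  cfg <- design_config("exp1", n_per_group = c(without = 6, with = 6),
                       seed = 5)
  t1 <- simulate_experiment(cfg)
  t2 <- simulate_experiment(cfg)
  expect_identical(t1, t2)
  cfg2 <- design_config("exp1", n_per_group = c(without = 6, with = 6),
                        seed = 6)
  t3 <- simulate_experiment(cfg2)
  expect_false(identical(t1$jol, t3$jol))
  expect_false(identical(t1$test_response, t3$test_response))
})

test_that("room/object design arithmetic holds per participant", {
  cfg <- design_config("exp1", n_per_group = c(without = 3, with = 3),
                       seed = 1)
  tr <- simulate_experiment(cfg)
  for (p in unique(tr$participant)) {
    d <- tr[tr$participant == p, ]
    study <- d[d$phase == "study" & !d$buffer, ]
    expect_equal(nrow(study), 64L)
    expect_equal(sum(study$expectancy == "expected"), 32L)
    expect_equal(sum(study$expectancy == "unexpected"), 32L)
    expect_equal(sum(d$phase == "study" & d$buffer), 2L)
    test <- d[d$phase == "test", ]
    expect_equal(nrow(test), 96L)
    expect_equal(sum(!test$old), 32L)
    # per item type: 16 kitchen-source, 16 bathroom-source, 16 new
    for (ty in c("bathroom", "kitchen")) {
      tt <- test[test$item_type == ty, ]
      expect_equal(as.integer(table(tt$source)[c("kitchen", "bathroom",
                                                 "new")]),
                   c(16L, 16L, 16L))
    }
  }
})

test_that("item lists rotate through the three roles across participants", {
  cfg <- design_config("exp1", n_per_group = c(without = 3, with = 3),
                       seed = 2)
  tr <- simulate_experiment(cfg)
  role_of <- function(p) {
    d <- tr[tr$participant == p & tr$phase == "study" & !tr$buffer, ]
    lst <- (d$item_id - 1) %/% 32 + 1
    vapply(1:3, function(l) unique(d$source[lst == l])[1], "")
  }
  roles <- vapply(1:3, role_of, character(3))   # 3 lists x 3 participants
  for (l in 1:3) {
    served <- roles[l, ]
    expect_setequal(served[!is.na(served)], c("kitchen", "bathroom"))
    # the list absent from study served as distractors exactly once
    expect_equal(sum(is.na(served)), 1L)
  }
})

test_that("face/behavior design arithmetic and payoffs hold", {
  cfg <- design_config("exp2", n_per_group = c(without = 2, with = 2),
                       seed = 3)
  tr <- simulate_experiment(cfg)
  for (p in unique(tr$participant)) {
    d <- tr[tr$participant == p, ]
    study <- d[d$phase == "study" & !d$buffer, ]
    expect_equal(nrow(study), 40L)
    expect_equal(sum(d$phase == "study" & d$buffer), 2L)
    expect_equal(nrow(d[d$phase == "test", ]), 80L)
    expect_equal(sum(!d$old[d$phase == "test"]), 40L)
    # ten partners per trustworthiness x behavior cell
    tab <- table(study$item_type, study$source)
    expect_true(all(dim(tab) == c(2L, 2L)) && all(tab == 10L))
    expect_true(all(study$investment %in% c(15L, 30L)))
    coop <- study$source == "cooperation"
    expect_true(all(study$payoff[coop] ==
                      ifelse(study$investment[coop] == 30L, 10L, 5L)))
    expect_true(all(study$payoff[!coop] ==
                      ifelse(study$investment[!coop] == 30L, -10L, -5L)))
    lik <- d$likability[d$phase == "test"]
    expect_true(all(lik %in% 1:6))
  }
})

test_that("only the with-judgments group carries learning judgments", {
  cfg <- design_config("exp1", n_per_group = c(without = 4, with = 4),
                       seed = 4)
  tr <- simulate_experiment(cfg)
  study <- tr[tr$phase == "study", ]
  expect_true(all(is.na(study$jol[study$group == "without"])))
  expect_true(all(!is.na(study$jol[study$group == "with"])))
  expect_true(all(!is.na(study$jos[study$group == "with"])))
  expect_true(all(tr$jol[!is.na(tr$jol)] >= 0 &
                    tr$jol[!is.na(tr$jol)] <= 100))
})

test_that("degenerate judgment model collapses to the grand mean", {
  jm <- judgment_model(grand_mean = 40, jol_expectancy = 0,
                       jos_expectancy = 0, jol_expectancy_sd = 0,
                       jos_expectancy_sd = 0, post_expectancy_with = 0,
                       post_expectancy_without = 0, behavior_effect = 0,
                       participant_sd = 0, residual_sd = 0)
  cfg <- design_config("exp1", n_per_group = c(without = 2, with = 2),
                       judgments = jm, seed = 5, n_incomplete = 0)
  tr <- simulate_experiment(cfg)
  vals <- c(tr$jol, tr$jos)
  expect_true(all(vals[!is.na(vals)] == 40))
})

test_that("perfect memory yields diagonal frequency tables", {
  th <- lapply(default_theta("exp1"), function(x)
    htsm_par(1, 1, 1, x[["b"]], x[["g"]]))
  cfg <- design_config("exp1", n_per_group = c(without = 2, with = 2),
                       theta = th, seed = 6)
  agg <- aggregate_frequencies(simulate_experiment(cfg))
  for (tab in agg$tables) {
    m <- unclass(tab)
    expect_equal(sum(diag(m)), sum(m))
  }
})

test_that("aggregation tallies the drawn responses exactly", {
  cfg <- design_config("exp1", n_per_group = c(without = 2, with = 2),
                       seed = 7)
  tr <- simulate_experiment(cfg)
  agg <- aggregate_frequencies(tr)
  expect_equal(agg$N_total, 4 * 96)
  expect_equal(sum(vapply(agg$tables, sum, numeric(1))), agg$N_total)
  # oracle tally for one condition
  tst <- tr[tr$phase == "test" & tr$group == "with" &
              tr$item_type == "kitchen", ]
  cls <- ifelse(!tst$old, "new",
                ifelse(tst$source == "kitchen", "sourceA_old",
                       "sourceB_old"))
  manual <- table(cls, tst$test_response)
  m <- unclass(agg$tables[["with.kitchen"]])
  for (r in rownames(manual)) for (cc in colnames(manual)) {
    expect_equal(m[r, cc], unname(manual[r, cc]))
  }
  expect_error(aggregate_frequencies(tr[tr$phase == "study", ]),
               "no test-phase rows")
})

test_that("aggregated proportions converge to the category probabilities", {
  theta <- default_theta("exp2")
  cfg <- design_config("exp2", n_per_group = c(without = 100, with = 100),
                       theta = theta, seed = 8)
  agg <- aggregate_frequencies(simulate_experiment(cfg))
  for (cond in names(agg$tables)) {
    m <- unclass(agg$tables[[cond]])
    p_true <- category_probabilities(theta[[cond]])
    p_hat <- m / rowSums(m)
    se <- sqrt(p_true * (1 - p_true) / rowSums(m))
    expect_true(all(abs(p_hat - p_true) <= 3 * se + 1e-9),
                info = cond)
  }
})

test_that("corrected hit rate behaves as hit rate minus false alarms", {
  th_perfect <- lapply(default_theta("exp1"), function(x)
    htsm_par(1, 1, 1, 0.5, 0.5))
  cfg <- design_config("exp1", n_per_group = c(without = 1, with = 1),
                       theta = th_perfect, seed = 9)
  chr <- corrected_item_recognition(simulate_experiment(cfg))
  expect_true(all(chr$corrected == 1))

  # responder who calls everything old: D = 0, b = 1
  th_old <- lapply(default_theta("exp1"), function(x)
    htsm_par(0, 0.5, 0.5, 1, 0.5))
  cfg <- design_config("exp1", n_per_group = c(without = 1, with = 1),
                       theta = th_old, seed = 10)
  chr <- corrected_item_recognition(simulate_experiment(cfg))
  expect_true(all(chr$corrected == 0))

  # expected value D under the two-high-threshold closed form
  th_mid <- lapply(default_theta("exp1"), function(x)
    htsm_par(0.6, 0.4, 0.4, 0.3, 0.5))
  cfg <- design_config("exp1", n_per_group = c(without = 24, with = 24),
                       theta = th_mid, seed = 11)
  chr <- corrected_item_recognition(simulate_experiment(cfg))
  expect_equal(mean(chr$corrected), 0.6, tolerance = 0.03)
})

test_that("trial files round-trip through delimited text", {
  cfg <- design_config("exp2", n_per_group = c(without = 2, with = 2),
                       seed = 12)
  tr <- simulate_experiment(cfg)
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- read_trials(f)
  expect_equal(attr(back, "experiment"), "exp2")
  agg1 <- aggregate_frequencies(tr)
  agg2 <- aggregate_frequencies(back)
  expect_equal(lapply(agg1$tables, unclass), lapply(agg2$tables, unclass))
  unlink(f)
})

test_that("direct table simulation matches trial-level aggregation in law", {
  # same theta, comparable scale: cell probabilities agree within
  # Monte-Carlo error of both routes
  theta <- default_theta("exp1")["without.kitchen"]
  tabs <- simulate_tables(theta, c(3000, 3000, 3000), seed = 13)
  m <- unclass(tabs[[1]])
  p_true <- category_probabilities(theta[[1]])
  se <- sqrt(p_true * (1 - p_true) / 3000)
  expect_true(all(abs(m / 3000 - p_true) <= 3.5 * se + 1e-9))
})
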