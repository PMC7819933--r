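# Contrast-score ANOVAs for the 0-100 judgment scales.

make_cm <- function(m, group = NULL) {
  cells <- c("t1.s1", "t1.s2", "t2.s1", "t2.s2")
  colnames(m) <- cells
  out <- data.frame(participant = seq_len(nrow(m)),
                    group = if (is.null(group)) "all" else group,
                    m, check.names = FALSE)
  attr(out, "cells") <- cells
  out
}

test_that("no effect pattern gives zero F, undefined only without error variance", {
  m <- matrix(50, 8, 4)               # identical cells everywhere
  a <- rm_anova_2x2(make_cm(m))
  expect_equal(a$F, c(0, 0, 0))
  # nonzero contrast with zero variance is flagged undefined
  m2 <- matrix(rep(c(60, 40, 40, 60), each = 8), 8, 4)
  a2 <- rm_anova_2x2(make_cm(m2))
  expect_true(is.na(a2$F[a2$effect == "interaction"]))
})

test_that("each within F equals the squared paired t of its contrast", {
  set.seed(1)
  m <- matrix(rnorm(60 * 4, 50, 10), 60, 4)
  a <- rm_anova_2x2(make_cm(m))
  t_type <- t.test((m[, 1] + m[, 2]) / 2, (m[, 3] + m[, 4]) / 2,
                   paired = TRUE)
  t_int <- t.test(m[, 1] - m[, 2], m[, 3] - m[, 4], paired = TRUE)
  expect_equal(a$F[a$effect == "type"], unname(t_type$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$effect == "type"], t_type$p.value, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "interaction"], unname(t_int$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$df2, rep(59L, 3))
})

test_that("mixed ANOVA agrees with aov on a balanced design", {
  set.seed(2)
  n <- 20
  m <- matrix(rnorm(2 * n * 4, 50, 8), 2 * n, 4)
  m[1:n, 1] <- m[1:n, 1] + 6          # perturb group 1
  grp <- rep(c("g1", "g2"), each = n)
  cm <- make_cm(m, group = grp)
  a <- mixed_anova_2x2x2(cm)

  long <- data.frame(
    y = as.vector(m),
    type = factor(rep(rep(c("t1", "t2"), each = 2 * 2 * n))),
    src = factor(rep(rep(c("s1", "s2"), each = 2 * n), times = 2)),
    grp = factor(rep(grp, times = 4)),
    id = factor(rep(seq_len(2 * n), times = 4)))
  fit <- summary(aov(y ~ type * src * grp + Error(id / (type * src)),
                     data = long))
  get_F <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(a$F[a$effect == "group"], get_F("Error: id", "grp"),
               tolerance = 1e-8)
  expect_equal(a$F[a$effect == "type"], get_F("Error: id:type", "type"),
               tolerance = 1e-8)
  expect_equal(a$F[a$effect == "type:group"],
               get_F("Error: id:type", "type:grp"), tolerance = 1e-8)
  expect_equal(a$F[a$effect == "source"], get_F("Error: id:src", "src"),
               tolerance = 1e-8)
  expect_equal(a$F[a$effect == "type:source"],
               get_F("Error: id:type:src", "type:src"), tolerance = 1e-8)
  expect_equal(a$F[a$effect == "type:source:group"],
               get_F("Error: id:type:src", "type:src:grp"),
               tolerance = 1e-8)
  expect_equal(a$df2, rep(2L * n - 2L, 7))
})

test_that("partial eta squared satisfies its 1-df identity and printed values", {
  set.seed(3)
  for (i in 1:50) {
    F <- rexp(1, 1 / 10); df2 <- sample(20:200, 1)
    expect_equal(partial_eta_sq(F, 1, df2), F / (F + df2),
                 tolerance = 1e-12)
  }
  expect_equal(round(partial_eta_sq(25.69, 1, 91), 2), 0.22)
  expect_equal(round(partial_eta_sq(26.57, 1, 59), 2), 0.31)
})

test_that("F survival function matches the squared-t identity and printed p", {
  expect_equal(f_sf(0, 1, 59), 1)
  expect_lt(abs(f_sf(5.64, 1, 59) - 0.021), 0.0025)
  set.seed(4)
  for (i in 1:20) {
    t <- rnorm(1, 0, 2); nu <- sample(10:100, 1)
    expect_equal(f_sf(t^2, 1, nu), 2 * pt(-abs(t), nu), tolerance = 1e-12)
  }
})

test_that("interaction rejection rate matches the noncentral-F power oracle", {
  n <- 60; delta <- 6; sigma <- 12
  lambda <- n * delta^2 / sigma^2     # interaction contrast mean delta
  pow <- pf(qf(0.95, 1, n - 1), 1, n - 1, ncp = lambda,
            lower.tail = FALSE)
  set.seed(5)
  n_rep <- 400
  reject <- 0
  for (r in 1:n_rep) {
    cs <- rnorm(n, delta, sigma)      # interaction contrast scores
    m <- cbind(cs / 2, 0, 0, cs / 2) + matrix(50, n, 4)
    a <- rm_anova_2x2(make_cm(m))
    reject <- reject + (a$p[a$effect == "interaction"] < 0.05)
  }
  se <- sqrt(pow * (1 - pow) / n_rep)
  expect_lt(abs(reject / n_rep - pow), 3.5 * se + 0.005)
})

test_that("three-way interaction localizes a single-group effect", {
  set.seed(6)
  n <- 50
  m1 <- matrix(rnorm(n * 4, 50, 8), n, 4)
  m1[, c(1, 4)] <- m1[, c(1, 4)] + 8   # interaction in group 1 only
  m2 <- matrix(rnorm(n * 4, 50, 8), n, 4)
  cm <- make_cm(rbind(m1, m2), group = rep(c("g1", "g2"), each = n))
  a <- mixed_anova_2x2x2(cm)
  expect_lt(a$p[a$effect == "type:source:group"], 0.05)
  se <- interaction_simple_effects(cm, alpha = 0.05, bonferroni = TRUE)
  expect_equal(attr(se, "alpha"), 0.025)
  expect_equal(se$decision, c("reject", "retain"))
  expect_equal(se$df2, c(n - 1L, n - 1L))
})

test_that("cell means exclude participants with missing cells and count them", {
  cfg <- design_config("exp1", n_per_group = c(without = 10, with = 10),
                       seed = 7, n_incomplete = 4)
  tr <- simulate_experiment(cfg)
  cm <- cell_means(tr, measure = "jos", phase = "postdiction")
  expect_equal(attr(cm, "n_excluded"), 4L)
  expect_equal(nrow(cm), 16L)
  expect_false(anyNA(cell_means(tr, "jol", "study")))
})

test_that("planted judgment expectancy effects are recovered from generated data", {
  jm <- judgment_model(jos_expectancy = 15, jol_expectancy = 0,
                       participant_sd = 5, residual_sd = 10)
  cfg <- design_config("exp1", n_per_group = c(without = 30, with = 30),
                       judgments = jm, seed = 8, n_incomplete = 0)
  tr <- simulate_experiment(cfg)
  a <- rm_anova_2x2(cell_means(tr, "jos", "study"))
  # expectancy = type x source interaction in this layout
  expect_lt(a$p[a$effect == "interaction"], 0.001)
  a_jol <- rm_anova_2x2(cell_means(tr, "jol", "study"))
  expect_gt(a_jol$p[a_jol$effect == "interaction"], 0.01)
})
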