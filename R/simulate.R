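# Seeded generator of synthetic source-monitoring experiments.
#
# Two designs are emulated.  The room/object design: two judgment groups,
# 96 objects in three counterbalanced lists of 32 (16 bathroom-typical and
# 16 kitchen-typical each); per participant one list is studied with the
# kitchen source, one with the bathroom source (32 expected + 32 unexpected
# pairs) and one serves as distractors, giving 96 test trials.  The
# face/behavior design: 40 game partners (10 per facial-trustworthiness x
# behavior cell) plus 40 new faces, giving 80 test trials, with game
# investment/payoff and test-phase likability columns emitted for schema
# fidelity.  A third, survey-style design emits 2 x 2 belief judgments
# only.  All numeric defaults below are synthetic and chosen to resemble
# plausible values for this paradigm; they are not estimates from any
# deposited dataset.

#' Additive generative model for 0-100 judgment scales
#'
#' Judgments (of learning, postdictions, beliefs) are generated as
#' `grand_mean + effects + participant intercept + residual noise`, clipped
#' to `[0, 100]`.  Effects are expressed in scale points.
#'
#' @param grand_mean scale mean.
#' @param jol_expectancy,jos_expectancy points added to expected
#'   item-source pairings in judgments of item / source learning
#'   (population mean of the effect).
#' @param jol_expectancy_sd,jos_expectancy_sd between-participant standard
#'   deviations of those expectancy effects (random slopes); participants
#'   differ in how strongly they show the illusion.
#' @param post_expectancy_with,post_expectancy_without points added to
#'   expected cells in postdictions, per judgment group (the illusion can
#'   be planted in one group only).
#' @param behavior_effect points added to cheating cells in postdictions
#'   and beliefs for the face/behavior designs.
#' @param participant_sd,residual_sd standard deviations of the participant
#'   intercept and the trial residual.
#' @return A list of class `"judgment_model"`.
#' @export
judgment_model <- function(grand_mean = 55,
                           jol_expectancy = 5, jos_expectancy = 10,
                           jol_expectancy_sd = 6.5,
                           jos_expectancy_sd = 8.5,
                           post_expectancy_with = 8,
                           post_expectancy_without = 0,
                           behavior_effect = 0,
                           participant_sd = 10, residual_sd = 15) {
  structure(list(grand_mean = grand_mean,
                 jol_expectancy = jol_expectancy,
                 jos_expectancy = jos_expectancy,
                 jol_expectancy_sd = jol_expectancy_sd,
                 jos_expectancy_sd = jos_expectancy_sd,
                 post_expectancy_with = post_expectancy_with,
                 post_expectancy_without = post_expectancy_without,
                 behavior_effect = behavior_effect,
                 participant_sd = participant_sd,
                 residual_sd = residual_sd),
            class = "judgment_model")
}

#' Default synthetic model parameters per condition
#'
#' One [htsm_par()] vector per `"<group>.<type>"` condition.  The defaults
#' plant the structure the analyses are designed to detect: better item
#' memory in the with-judgments group, an expectancy-violation advantage
#' (`d_unexpected > d_expected`) in the without-judgments group only, and
#' a schematic source-guessing bias (`g` pulled toward the
#' schema-consistent source).  Effect magnitudes are calibrated so that at
#' the default design sizes the implied noncentralities of the planned
#' likelihood-ratio tests are of the order of magnitude such studies
#' report; the individual probabilities are synthetic.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return Named list of [htsm_par()] vectors.
#' @export
default_theta <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    # Source A = kitchen.  For bathroom items d_B is the expected pairing,
    # for kitchen items d_A is.
    list(
      without.bathroom = htsm_par(0.55, d_A = 0.43, d_B = 0.21, b = 0.37,
                                  g = 0.38),
      without.kitchen  = htsm_par(0.55, d_A = 0.21, d_B = 0.43, b = 0.26,
                                  g = 0.60),
      with.bathroom    = htsm_par(0.71, d_A = 0.37, d_B = 0.35, b = 0.36,
                                  g = 0.40),
      with.kitchen     = htsm_par(0.71, d_A = 0.35, d_B = 0.37, b = 0.32,
                                  g = 0.60))
  } else {
    # Source A = cheating.  For trustworthy faces d_B (cooperation) is the
    # expected pairing, for untrustworthy faces d_A (cheating) is.
    list(
      without.trustworthy   = htsm_par(0.60, d_A = 0.45, d_B = 0.15,
                                       b = 0.24, g = 0.38),
      without.untrustworthy = htsm_par(0.63, d_A = 0.15, d_B = 0.45,
                                       b = 0.22, g = 0.70),
      with.trustworthy      = htsm_par(0.69, d_A = 0.32, d_B = 0.30,
                                       b = 0.30, g = 0.45),
      with.untrustworthy    = htsm_par(0.72, d_A = 0.30, d_B = 0.32,
                                       b = 0.29, g = 0.66))
  }
}

#' Configuration of a synthetic experiment
#'
#' @param experiment `"exp1"` (rooms x objects), `"exp2"` (faces x
#'   cheating/cooperation) or `"exp3"` (belief survey).
#' @param n_per_group named integer vector of participants per judgment
#'   group.  Defaults: exp1 `c(without = 60, with = 60)`; exp2
#'   `c(without = 93, with = 92)`; exp3 `c(with = 100)` (survey
#'   respondents).
#' @param seed integer seed; the same config and seed reproduce the output
#'   exactly.
#' @param theta named list of [htsm_par()] per condition (ignored for
#'   exp3); defaults to [default_theta()].
#' @param judgments a [judgment_model()]; sensible defaults per experiment.
#' @param n_incomplete number of participants whose postdictions are
#'   missing (listwise-excluded downstream).  Default 18 for exp1, 0
#'   otherwise.
#' @return A list of class `"design_config"`.
#' @export
design_config <- function(experiment = c("exp1", "exp2", "exp3"),
                          n_per_group = NULL, seed = 1L, theta = NULL,
                          judgments = NULL, n_incomplete = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(n_per_group)) {
    n_per_group <- switch(experiment,
                          exp1 = c(without = 60L, with = 60L),
                          exp2 = c(without = 93L, with = 92L),
                          exp3 = c(with = 100L))
  }
  if (experiment != "exp3" &&
      !all(sort(names(n_per_group)) == c("with", "without"))) {
    stop("'n_per_group' must name the groups 'without' and 'with'",
         call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("need at least one participant per group",
                                 call. = FALSE)
  if (is.null(theta) && experiment != "exp3") {
    theta <- default_theta(experiment)
  }
  if (experiment != "exp3") {
    conds <- as.vector(outer(names(n_per_group),
                             type_levels(experiment), paste, sep = "."))
    missing <- setdiff(conds, names(theta))
    if (length(missing)) {
      stop("'theta' lacks condition(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(judgments)) {
    judgments <- switch(experiment,
      exp1 = judgment_model(),
      exp2 = judgment_model(jol_expectancy = 0, jos_expectancy = 5,
                            jol_expectancy_sd = 5,
                            post_expectancy_with = 0,
                            post_expectancy_without = 0,
                            behavior_effect = 5),
      exp3 = judgment_model(jol_expectancy = 0, jos_expectancy = 0,
                            behavior_effect = 6))
  }
  if (is.null(n_incomplete)) {
    n_incomplete <- if (experiment == "exp1") 18L else 0L
  }
  structure(list(experiment = experiment, n_per_group = n_per_group,
                 seed = as.integer(seed), theta = theta,
                 judgments = judgments,
                 n_incomplete = as.integer(n_incomplete)),
            class = "design_config")
}

type_levels <- function(experiment) {
  switch(experiment,
         exp1 = c("bathroom", "kitchen"),
         exp2 = c("trustworthy", "untrustworthy"))
}

source_levels <- function(experiment) {
  # Source A first.
  switch(experiment,
         exp1 = c("kitchen", "bathroom"),
         exp2 = c("cheating", "cooperation"))
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

clip100 <- function(x) pmin(pmax(x, 0), 100)

#' Generate a synthetic experiment
#'
#' Produces a trial-level data frame with one row per study, test,
#' postdiction or belief event.  Test responses are drawn from the
#' [category_probabilities()] of the condition's parameter vector;
#' judgments from the additive [judgment_model()].  Buffer/practice trials
#' are emitted but flagged (`buffer = TRUE`) and carry no test rows.
#' Output is reproducible given the config's seed.
#'
#' @param config a [design_config()].
#' @return A data frame with columns `participant`, `group`, `phase`,
#'   `item_id`, `item_type`, `source`, `expectancy`, `buffer`, `old`,
#'   `jol`, `jos`, `test_response`, `investment`, `payoff`, `likability`,
#'   and an `experiment` attribute.  In postdiction and belief rows, `jol`
#'   holds the item-memory and `jos` the source-memory judgment for the
#'   cell given by `item_type` and `source`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "design_config"))
  with_seed(config$seed, {
    trials <- switch(config$experiment,
                     exp1 = simulate_exp1(config),
                     exp2 = simulate_exp2(config),
                     exp3 = simulate_exp3(config))
  })
  attr(trials, "experiment") <- config$experiment
  trials
}

# Shared machinery: draw one test response per trial from the category
# probabilities of its (condition, item class) cell.
draw_responses <- function(condition, item_class, theta) {
  out <- character(length(condition))
  for (cond in unique(condition)) {
    p <- category_probabilities(theta[[cond]])
    for (cls in unique(item_class[condition == cond])) {
      idx <- which(condition == cond & item_class == cls)
      out[idx] <- sample(RESPONSES, length(idx), replace = TRUE,
                         prob = p[cls, ])
    }
  }
  out
}

participant_frame <- function(n_per_group) {
  data.frame(participant = seq_len(sum(n_per_group)),
             group = rep(names(n_per_group), times = n_per_group))
}

judgment_draw <- function(mu, u, sd_res) {
  clip100(mu + u + stats::rnorm(length(mu), 0, sd_res))
}

simulate_exp1 <- function(config) {
  jm <- config$judgments
  pts <- participant_frame(config$n_per_group)
  n <- nrow(pts)
  u <- stats::rnorm(n, 0, jm$participant_sd)

  # 96 items in three lists of 32; within each list 16 bathroom-typical
  # then 16 kitchen-typical items.
  item_list <- rep(1:3, each = 32)
  item_type_all <- rep(rep(c("bathroom", "kitchen"), each = 16), times = 3)

  one_participant <- function(p) {
    role <- (p + 0:2 - 1) %% 3 + 1           # kitchen, bathroom, distractor
    kitchen_list <- role[1]; bathroom_list <- role[2]
    studied <- item_list != role[3]
    src <- ifelse(item_list == kitchen_list, "kitchen",
                  ifelse(item_list == bathroom_list, "bathroom", "new"))
    exp_flag <- ifelse(src == "new", NA_character_,
                       ifelse(src == item_type_all, "expected",
                              "unexpected"))
    grp <- pts$group[p]

    study_idx <- sample(which(studied))       # randomized study order
    study <- data.frame(
      participant = p, group = grp, phase = "study",
      item_id = c(-1L, -2L, study_idx),
      item_type = c("buffer", "buffer", item_type_all[study_idx]),
      source = c("kitchen", "bathroom", src[study_idx]),
      expectancy = c(NA, NA, exp_flag[study_idx]),
      buffer = c(TRUE, TRUE, rep(FALSE, length(study_idx))),
      old = TRUE, stringsAsFactors = FALSE)
    if (grp == "with") {
      # participant-specific expectancy effects (random slopes)
      eff_jol <- stats::rnorm(1, jm$jol_expectancy, jm$jol_expectancy_sd)
      eff_jos <- stats::rnorm(1, jm$jos_expectancy, jm$jos_expectancy_sd)
      mu_jol <- jm$grand_mean + eff_jol * (study$expectancy %in% "expected")
      mu_jos <- jm$grand_mean + eff_jos * (study$expectancy %in% "expected")
      study$jol <- judgment_draw(mu_jol, u[p], jm$residual_sd)
      study$jos <- judgment_draw(mu_jos, u[p], jm$residual_sd)
    } else {
      study$jol <- NA_real_; study$jos <- NA_real_
    }

    test_idx <- sample(96L)                   # all items, random order
    test <- data.frame(
      participant = p, group = grp, phase = "test",
      item_id = test_idx,
      item_type = item_type_all[test_idx],
      source = src[test_idx],
      expectancy = exp_flag[test_idx],
      buffer = FALSE, old = src[test_idx] != "new",
      jol = NA_real_, jos = NA_real_, stringsAsFactors = FALSE)

    post <- expand.grid(item_type = c("bathroom", "kitchen"),
                        source = c("kitchen", "bathroom"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    post_exp <- ifelse(post$item_type == post$source, "expected",
                       "unexpected")
    eff <- if (grp == "with") jm$post_expectancy_with else
      jm$post_expectancy_without
    mu_post <- jm$grand_mean + eff * (post_exp == "expected")
    post <- data.frame(
      participant = p, group = grp, phase = "postdiction",
      item_id = NA_integer_, item_type = post$item_type,
      source = post$source, expectancy = post_exp, buffer = FALSE,
      old = NA,
      jol = judgment_draw(mu_post, u[p], jm$residual_sd),
      jos = judgment_draw(mu_post, u[p], jm$residual_sd),
      stringsAsFactors = FALSE)
    rbind(study, test, post)
  }

  trials <- do.call(rbind, lapply(seq_len(n), one_participant))

  # test responses, drawn per condition x item class
  ti <- trials$phase == "test"
  cls <- ifelse(!trials$old[ti], "new",
                ifelse(trials$source[ti] == "kitchen", "sourceA_old",
                       "sourceB_old"))
  cond <- paste(trials$group[ti], trials$item_type[ti], sep = ".")
  trials$test_response <- NA_character_
  trials$test_response[ti] <- draw_responses(cond, cls, config$theta)

  if (config$n_incomplete > 0) {
    drop <- sample(n, min(config$n_incomplete, n))
    sel <- trials$phase == "postdiction" & trials$participant %in% drop
    trials$jol[sel] <- NA_real_
    trials$jos[sel] <- NA_real_
  }
  trials$investment <- NA_integer_
  trials$payoff <- NA_integer_
  trials$likability <- NA_integer_
  rownames(trials) <- NULL
  trials
}

simulate_exp2 <- function(config) {
  jm <- config$judgments
  pts <- participant_frame(config$n_per_group)
  n <- nrow(pts)
  u <- stats::rnorm(n, 0, jm$participant_sd)

  # Partners 1..40 (studied), new faces 41..80.  Ten faces per
  # trustworthiness x behavior cell; new faces split by trustworthiness.
  face_type <- rep(c("trustworthy", "untrustworthy", "trustworthy",
                     "untrustworthy"), times = c(20, 20, 20, 20))
  face_beh <- c(rep(c("cheating", "cooperation"), each = 10),
                rep(c("cheating", "cooperation"), each = 10),
                rep("new", 40))

  one_participant <- function(p) {
    grp <- pts$group[p]
    game_idx <- sample(1:40)
    exp_flag <- ifelse((face_type == "trustworthy" &
                          face_beh == "cooperation") |
                         (face_type == "untrustworthy" &
                            face_beh == "cheating"),
                       "expected",
                       ifelse(face_beh == "new", NA_character_,
                              "unexpected"))
    invest <- sample(c(15L, 30L), 42, replace = TRUE)
    study_beh <- c(sample(c("cheating", "cooperation"), 2, replace = TRUE),
                   face_beh[game_idx])
    payoff <- ifelse(study_beh == "cooperation",
                     ifelse(invest == 30L, 10L, 5L),
                     ifelse(invest == 30L, -10L, -5L))
    study <- data.frame(
      participant = p, group = grp, phase = "study",
      item_id = c(-1L, -2L, game_idx),
      item_type = c("practice", "practice", face_type[game_idx]),
      source = study_beh,
      expectancy = c(NA, NA, exp_flag[game_idx]),
      buffer = c(TRUE, TRUE, rep(FALSE, 40)),
      old = TRUE, investment = invest, payoff = payoff,
      stringsAsFactors = FALSE)
    if (grp == "with") {
      eff_jol <- stats::rnorm(1, jm$jol_expectancy, jm$jol_expectancy_sd)
      eff_jos <- stats::rnorm(1, jm$jos_expectancy, jm$jos_expectancy_sd)
      mu_jol <- jm$grand_mean + eff_jol * (study$expectancy %in% "expected")
      mu_jos <- jm$grand_mean + eff_jos * (study$expectancy %in% "expected")
      study$jol <- judgment_draw(mu_jol, u[p], jm$residual_sd)
      study$jos <- judgment_draw(mu_jos, u[p], jm$residual_sd)
    } else {
      study$jol <- NA_real_; study$jos <- NA_real_
    }

    test_idx <- sample(80L)
    lik_mu <- ifelse(face_type[test_idx] == "trustworthy", 3.6, 2.5) +
      0.15 * (face_beh[test_idx] == "cooperation")
    test <- data.frame(
      participant = p, group = grp, phase = "test",
      item_id = test_idx, item_type = face_type[test_idx],
      source = face_beh[test_idx], expectancy = exp_flag[test_idx],
      buffer = FALSE, old = face_beh[test_idx] != "new",
      investment = NA_integer_, payoff = NA_integer_,
      jol = NA_real_, jos = NA_real_,
      likability = pmin(pmax(round(lik_mu + stats::rnorm(80, 0, 0.9)), 1L),
                        6L),
      stringsAsFactors = FALSE)
    study$likability <- NA_integer_

    post <- expand.grid(item_type = c("trustworthy", "untrustworthy"),
                        source = c("cheating", "cooperation"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    post_exp <- ifelse((post$item_type == "trustworthy" &
                          post$source == "cooperation") |
                         (post$item_type == "untrustworthy" &
                            post$source == "cheating"),
                       "expected", "unexpected")
    eff <- if (grp == "with") jm$post_expectancy_with else
      jm$post_expectancy_without
    mu_post <- jm$grand_mean + eff * (post_exp == "expected") +
      jm$behavior_effect * (post$source == "cheating")
    post <- data.frame(
      participant = p, group = grp, phase = "postdiction",
      item_id = NA_integer_, item_type = post$item_type,
      source = post$source, expectancy = post_exp, buffer = FALSE,
      old = NA, investment = NA_integer_, payoff = NA_integer_,
      jol = judgment_draw(mu_post, u[p], jm$residual_sd),
      jos = judgment_draw(mu_post, u[p], jm$residual_sd),
      likability = NA_integer_, stringsAsFactors = FALSE)
    rbind(study, test, post)
  }

  trials <- do.call(rbind, lapply(seq_len(n), one_participant))

  ti <- trials$phase == "test"
  cls <- ifelse(!trials$old[ti], "new",
                ifelse(trials$source[ti] == "cheating", "sourceA_old",
                       "sourceB_old"))
  cond <- paste(trials$group[ti], trials$item_type[ti], sep = ".")
  trials$test_response <- NA_character_
  trials$test_response[ti] <- draw_responses(cond, cls, config$theta)

  if (config$n_incomplete > 0) {
    drop <- sample(n, min(config$n_incomplete, n))
    sel <- trials$phase == "postdiction" & trials$participant %in% drop
    trials$jol[sel] <- NA_real_
    trials$jos[sel] <- NA_real_
  }
  rownames(trials) <- NULL
  trials
}

simulate_exp3 <- function(config) {
  jm <- config$judgments
  n <- sum(config$n_per_group)
  u <- stats::rnorm(n, 0, jm$participant_sd)
  cells <- expand.grid(item_type = c("trustworthy", "untrustworthy"),
                       source = c("cheating", "cooperation"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n), function(p) {
    mu <- jm$grand_mean + jm$behavior_effect * (cells$source == "cheating")
    data.frame(
      participant = p, group = "survey", phase = "belief",
      item_id = NA_integer_, item_type = cells$item_type,
      source = cells$source, expectancy = NA_character_, buffer = FALSE,
      old = NA, jol = judgment_draw(mu, u[p], jm$residual_sd),
      jos = judgment_draw(mu, u[p], jm$residual_sd),
      test_response = NA_character_, investment = NA_integer_,
      payoff = NA_integer_, likability = NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate test trials into per-condition frequency tables
#'
#' Tallies test-phase responses into one 3x3 [frequency_table()] per
#' (judgment group x item/face type) condition.  Source A is the kitchen
#' source in the room/object design and cheating in the face/behavior
#' design.  Buffer trials are excluded.
#'
#' @param trials a data frame from [simulate_experiment()] (or read from
#'   its delimited export); must carry an `experiment` attribute or be
#'   accompanied by the `experiment` argument.
#' @param experiment `"exp1"` or `"exp2"`; defaults to the attribute.
#' @return A list with `tables` (named list of [frequency_table()]s) and
#'   `N_total` (total number of test responses).
#' @export
aggregate_frequencies <- function(trials, experiment = NULL) {
  if (is.null(experiment)) experiment <- attr(trials, "experiment")
  if (is.null(experiment)) {
    stop("'experiment' not given and trials carry no experiment attribute",
         call. = FALSE)
  }
  tst <- trials[trials$phase == "test" & !trials$buffer, ]
  if (nrow(tst) == 0L) stop("no test-phase rows in input", call. = FALSE)
  bad <- setdiff(unique(tst$test_response), RESPONSES)
  if (length(bad)) {
    stop("unknown response code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  srcA <- source_levels(experiment)[1]
  cls <- ifelse(!tst$old, "new",
                ifelse(tst$source == srcA, "sourceA_old", "sourceB_old"))
  cond <- paste(tst$group, tst$item_type, sep = ".")
  tabs <- lapply(split(seq_len(nrow(tst)), cond), function(idx) {
    m <- table(factor(cls[idx], levels = ITEM_CLASSES),
               factor(tst$test_response[idx], levels = RESPONSES))
    frequency_table(unclass(m))
  })
  for (nm in names(tabs)) attr(tabs[[nm]], "label") <- nm
  list(tables = tabs, N_total = nrow(tst))
}

#' Corrected hit rate for item recognition
#'
#' Hit rate minus false-alarm rate per participant and item/face type,
#' where a hit is any "old" response (source A or source B) to a studied
#' item and a false alarm is any "old" response to a new item.  Under the
#' two-high-threshold model the expected value is `D`.
#'
#' @inheritParams aggregate_frequencies
#' @return A data frame with `participant`, `group`, `item_type`,
#'   `hit_rate`, `fa_rate`, `corrected` (NA with a warning-free flag when a
#'   denominator is zero).
#' @export
corrected_item_recognition <- function(trials) {
  tst <- trials[trials$phase == "test" & !trials$buffer, ]
  if (nrow(tst) == 0L) stop("no test-phase rows in input", call. = FALSE)
  old_resp <- tst$test_response != "respNew"
  key <- interaction(tst$participant, tst$group, tst$item_type, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(tst)), key), function(idx) {
    d <- tst[idx, ]
    n_old <- sum(d$old); n_new <- sum(!d$old)
    hr <- if (n_old > 0) sum(old_resp[idx] & d$old) / n_old else NA_real_
    fa <- if (n_new > 0) sum(old_resp[idx] & !d$old) / n_new else NA_real_
    data.frame(participant = d$participant[1], group = d$group[1],
               item_type = d$item_type[1], hit_rate = hr, fa_rate = fa,
               corrected = hr - fa)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$participant, out$item_type), ]
}

#' Directly simulate aggregated frequency tables
#'
#' Fast path for simulation studies: draws the per-row multinomial counts
#' of each condition's 3x3 table directly from the model's category
#' probabilities, which is distributionally identical to generating and
#' aggregating trial-level records.
#'
#' @param theta named list of [htsm_par()] per condition.
#' @param n_per_row named list (or single vector) of the three row totals
#'   (Source-A old, Source-B old, new trials) per condition.
#' @param seed optional integer seed.
#' @return Named list of [frequency_table()]s.
#' @export
simulate_tables <- function(theta, n_per_row, seed = NULL) {
  draw <- function() {
    lapply(stats::setNames(names(theta), names(theta)), function(cond) {
      p <- category_probabilities(theta[[cond]])
      n <- if (is.list(n_per_row)) n_per_row[[cond]] else n_per_row
      m <- t(vapply(1:3, function(i) {
        as.vector(stats::rmultinom(1, n[i], p[i, ]))
      }, numeric(3)))
      frequency_table(m, label = cond)
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Export trials as delimited text
#'
#' @param trials a data frame from [simulate_experiment()].
#' @param file output path; comma-separated with a header, plus the
#'   experiment tag in a leading comment-free `experiment` column.
#' @export
write_trials <- function(trials, file) {
  out <- trials
  out$experiment <- attr(trials, "experiment")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  exp <- unique(df$experiment)
  df$experiment <- NULL
  attr(df, "experiment") <- exp
  df
}
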