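# End-to-end orchestration: simulate (or load) -> aggregate -> model fits
# and nested comparisons -> judgment ANOVAs -> sensitivity power sweep,
# with machine-readable report tables.

#' Run the full analysis pipeline
#'
#' Executes every stage of the workflow on one experiment: generate (or
#' accept) trial-level data, aggregate to frequency tables, run the nested
#' source-monitoring model analysis, the judgment/postdiction ANOVAs with
#' simple-effect follow-ups, and the sensitivity power sweep.  The run is
#' fully determined by the config (including its seed).
#'
#' @param config a [design_config()] for `"exp1"` or `"exp2"`; for
#'   `"exp3"` only the belief ANOVA stage applies.
#' @param trials optional pre-loaded trial data (e.g. from
#'   [read_trials()]); when supplied the simulation stage is skipped.
#' @param alpha significance level for decisions (simple effects use
#'   `alpha / 2`).
#' @return A list of class `"sm_report"`: `trials`, `tables`, `analysis`
#'   (a [source_memory_analysis()] result), `guessing` (Table-style b/g
#'   estimates with CIs), `anovas` (list of `"anova_table"`s),
#'   `simple_effects`, `power` (df sweep of minimal detectable w), `config`
#'   and `seed`.
#' @export
run_pipeline <- function(config, trials = NULL, alpha = 0.05) {
  stopifnot(inherits(config, "design_config"))
  if (is.null(trials)) trials <- simulate_experiment(config)

  if (config$experiment == "exp3") {
    cm <- cell_means(trials, measure = "jos", phase = "belief")
    cmi <- cell_means(trials, measure = "jol", phase = "belief")
    out <- list(trials = trials, tables = NULL, analysis = NULL,
                guessing = NULL,
                anovas = list(belief_item = rm_anova_2x2(cmi),
                              belief_source = rm_anova_2x2(cm)),
                simple_effects = NULL, power = NULL,
                config = config, seed = config$seed)
    return(structure(out, class = "sm_report"))
  }

  agg <- aggregate_frequencies(trials)
  analysis <- source_memory_analysis(agg$tables, config$experiment,
                                     alpha = alpha, seed = config$seed)

  anovas <- list()
  simple <- list()
  with_cm <- function(measure, phase) {
    tryCatch(cell_means(trials, measure, phase), error = function(e) NULL)
  }
  cm_jol <- with_cm("jol", "study")
  cm_jos <- with_cm("jos", "study")
  if (!is.null(cm_jol) && nrow(cm_jol) > 1) {
    anovas$jol <- rm_anova_2x2(cm_jol)
    anovas$jos <- rm_anova_2x2(cm_jos)
  }
  cm_post_i <- with_cm("jol", "postdiction")
  cm_post_s <- with_cm("jos", "postdiction")
  if (!is.null(cm_post_i)) {
    anovas$postdiction_item <- mixed_anova_2x2x2(cm_post_i)
    anovas$postdiction_source <- mixed_anova_2x2x2(cm_post_s)
    simple$postdiction_item <- interaction_simple_effects(cm_post_i,
                                                          alpha = alpha)
    simple$postdiction_source <- interaction_simple_effects(cm_post_s,
                                                            alpha = alpha)
  }

  power <- sensitivity_sweep(alpha = alpha, power = 0.95,
                             N_total = agg$N_total)

  structure(list(trials = trials, tables = agg$tables,
                 analysis = analysis, guessing = guessing_table(analysis),
                 anovas = anovas, simple_effects = simple, power = power,
                 config = config, seed = config$seed),
            class = "sm_report")
}

#' @export
print.sm_report <- function(x, ...) {
  cat("Source-monitoring pipeline report (", x$config$experiment,
      ", seed ", x$seed, ")\n\n", sep = "")
  if (!is.null(x$analysis)) print(x$analysis)
  for (nm in names(x$anovas)) {
    cat("\nANOVA [", nm, "]:\n", sep = "")
    print(x$anovas[[nm]])
  }
  invisible(x)
}

#' Write a report bundle as delimited text and JSON
#'
#' Emits `comparisons.csv`, `fit.csv`, `guessing.csv`, `anova_<name>.csv`,
#' `power.csv`, `frequencies.csv`, `trials.csv` and (when jsonlite is
#' installed) `report.json` into `dir`.
#'
#' @param report an [run_pipeline()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(report$analysis)) {
    cmp <- report$analysis$comparisons
    cmp$delta_G2 <- round(cmp$delta_G2, 6)
    cmp$p <- round(cmp$p, 3); cmp$w <- round(cmp$w, 2)
    w(cmp, "comparisons.csv")
    w(transform(report$analysis$fit_rows, G2 = round(G2, 6),
                p = round(p, 3)), "fit.csv")
    w(report$guessing, "guessing.csv")
    w(transform(report$power, lambda = round(lambda, 6),
                w = round(w, 6)), "power.csv")
    write_frequency_tables(report$tables, file.path(dir,
                                                    "frequencies.csv"))
  }
  for (nm in names(report$anovas)) {
    a <- as.data.frame(report$anovas[[nm]])
    a$F <- round(a$F, 6); a$p <- round(a$p, 3)
    a$eta_p2 <- round(a$eta_p2, 6)
    w(a, paste0("anova_", nm, ".csv"))
  }
  write_trials(report$trials, file.path(dir, "trials.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- list(experiment = report$config$experiment, seed = report$seed,
               fit = if (!is.null(report$analysis))
                 report$analysis$fit_rows,
               comparisons = if (!is.null(report$analysis))
                 report$analysis$comparisons,
               guessing = report$guessing)
    jsonlite::write_json(js, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
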