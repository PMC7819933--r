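# Nested-model G-squared difference tests and the standard analysis plan
# for a 2 (item/face type) x 2 (judgment group) source-monitoring design.

#' Likelihood-ratio comparison of two nested fits
#'
#' Tests the restrictions that turn `full` into `nested` via
#' \eqn{\Delta G^2 = G^2_{nested} - G^2_{full}} on
#' \eqn{\Delta df = df_{nested} - df_{full}} degrees of freedom, with the
#' p-value from the central chi-square distribution and Cohen's w computed
#' from the total number of responses.  The nested spec must be a
#' coarsening of the full spec's symbol partition on the same data; small
#' negative differences from finite optimizer tolerance are clipped to zero
#' with a warning.
#'
#' @param nested,full [fit_mpt()] results on the same data; `nested` has
#'   fewer free symbols (more constraints).
#' @param labels optional character vector of length 2 naming the models.
#' @return An object of class `"mpt_comparison"` with elements `delta_G2`,
#'   `delta_df`, `p_value`, `w`, `N_total`, `nested_label`, `full_label`.
#' @export
compare_models <- function(nested, full,
                           labels = c("nested", "full")) {
  stopifnot(inherits(nested, "mpt_fit"), inherits(full, "mpt_fit"))
  if (nested$N_total != full$N_total ||
      !identical(nested$spec$tree_sets, full$spec$tree_sets)) {
    stop("fits must be on the same data (same tree sets and N)",
         call. = FALSE)
  }
  check_nested(nested$spec, full$spec)
  delta_df <- nested$df - full$df
  if (delta_df < 0) {
    stop("'nested' must not have more free symbols than 'full'",
         call. = FALSE)
  }
  delta <- nested$G2 - full$G2
  if (delta < 0) {
    if (delta < -1e-4) {
      stop("nested model fits better than full model beyond optimizer ",
           "tolerance (delta G2 = ", format(delta), "); not nested?",
           call. = FALSE)
    }
    warning("small negative delta G2 (", format(delta),
            ") clipped to 0", call. = FALSE)
    delta <- 0
  }
  structure(list(delta_G2 = delta, delta_df = delta_df,
                 p_value = if (delta_df == 0) 1 else
                   chi2_sf(delta, delta_df),
                 w = cohens_w(delta, nested$N_total),
                 N_total = nested$N_total,
                 nested_label = labels[1], full_label = labels[2]),
            class = "mpt_comparison")
}

# The nested spec's partition of (condition, parameter) cells must be a
# coarsening of the full spec's partition, and fixed cells must stay fixed
# at the same value.
check_nested <- function(nested_spec, full_spec) {
  key <- paste(full_spec$map$condition, full_spec$map$parameter)
  nk <- paste(nested_spec$map$condition, nested_spec$map$parameter)
  full_sym <- full_spec$map$symbol[match(key, key)]
  nested_sym <- nested_spec$map$symbol[match(key, nk)]
  for (s in unique(full_sym)) {
    cells <- which(full_sym == s)
    if (length(unique(nested_sym[cells])) != 1L) {
      stop("specs are not nested: cells sharing symbol '", s,
           "' in the full model map to different symbols in the nested ",
           "model", call. = FALSE)
    }
  }
  for (s in names(full_spec$fixed)) {
    cells <- which(full_sym == s)
    ns <- unique(nested_sym[cells])
    if (!ns %in% names(nested_spec$fixed) ||
        nested_spec$fixed[ns] != full_spec$fixed[s]) {
      stop("specs are not nested: fixed symbol '", s,
           "' is not fixed to the same value in the nested model",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: dG2(%d) = %.2f, p = %.3f, w = %.2f\n",
              x$nested_label, x$full_label, x$delta_df, x$delta_G2,
              x$p_value, x$w))
  invisible(x)
}

# ---- analysis plan -------------------------------------------------------

# Conditions are "<group>.<type>"; groups are the judgment groups and types
# the item/face types.  Which of d_A / d_B is the *expected* pairing
# depends on the experiment's Source-A meaning:
#   exp1: Source A = kitchen -> expected is d_A for kitchen items, d_B for
#         bathroom items.
#   exp2: Source A = cheating -> expected is d_A for untrustworthy faces,
#         d_B for trustworthy faces.
expected_source_param <- function(type, experiment) {
  switch(experiment,
         exp1 = ifelse(type == "kitchen", "d_A", "d_B"),
         exp2 = ifelse(type == "untrustworthy", "d_A", "d_B"),
         stop("unknown experiment: ", experiment, call. = FALSE))
}

#' Condition design of a four-tree-set experiment
#'
#' Builds the group x type layout that [source_memory_analysis()] needs
#' from condition labels of the form `"<group>.<type>"`.
#'
#' @param conditions character vector of four condition labels.
#' @return A data frame with columns `condition`, `group`, `type`.
#' @export
condition_design <- function(conditions) {
  parts <- strsplit(conditions, ".", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("condition labels must have the form '<group>.<type>'",
         call. = FALSE)
  }
  data.frame(condition = conditions,
             group = vapply(parts, `[`, "", 1L),
             type = vapply(parts, `[`, "", 2L))
}

#' Full nested-model analysis of a 2 x 2 source-monitoring design
#'
#' Runs the standard sequence of fits and likelihood-ratio tests on four
#' frequency tables (item/face type x judgment group):
#' \enumerate{
#'   \item base model: one `D` per tree set (old and new items share `D`),
#'     separate `d_A`, `d_B`, `b`, `g` per set; df 4.
#'   \item item memory by type: `D` equated across types within each group
#'     (delta-df 2, against the base model).
#'   \item item memory by group: `D` equated across groups within each type
#'     (delta-df 2, against the base model).
#'   \item expectancy-equated base: within each group one shared source
#'     memory parameter for expected pairings and one for unexpected
#'     pairings; df 8.  Used as the reference for the remaining tests.
#'   \item expectancy violation per group: `d_expected = d_unexpected`
#'     within each group (delta-df 1 each).
#'   \item source memory by group: both `d` symbols equated across groups
#'     (delta-df 2).
#'   \item guessing bias per group: `g` equated across types within each
#'     group (delta-df 1 each).
#' }
#'
#' @param tables named list of four [frequency_table()]s; names are
#'   `"<group>.<type>"` condition labels.
#' @param experiment `"exp1"` (Source A = kitchen; types bathroom/kitchen)
#'   or `"exp2"` (Source A = cheating; types trustworthy/untrustworthy).
#' @param alpha significance level for the decision column.
#' @param n_restarts,seed passed to [fit_mpt()].
#' @return An object of class `"sm_analysis"`: the list of `fits`, a
#'   `comparisons` data frame (`test,label,delta_G2,delta_df,p,w,decision`)
#'   and a `fit_rows` data frame with the two absolute goodness-of-fit
#'   tests (base and expectancy-equated model).
#' @export
source_memory_analysis <- function(tables,
                                   experiment = c("exp1", "exp2"),
                                   alpha = 0.05, n_restarts = 10,
                                   seed = 1L) {
  experiment <- match.arg(experiment)
  if (length(tables) != 4L || is.null(names(tables))) {
    stop("'tables' must be a named list of four frequency tables",
         call. = FALSE)
  }
  des <- condition_design(names(tables))
  groups <- unique(des$group)
  types <- unique(des$type)
  if (length(groups) != 2L || length(types) != 2L) {
    stop("conditions must cross two groups with two types", call. = FALSE)
  }

  base <- model_spec(des$condition)

  # (2) D equated across types within group
  spec_D_type <- base
  for (gr in groups) {
    conds <- des$condition[des$group == gr]
    spec_D_type <- equate(spec_D_type, paste("D", conds, sep = "."),
                          to = paste("D", gr, sep = "."))
  }
  # (3) D equated across groups within type
  spec_D_group <- base
  for (ty in types) {
    conds <- des$condition[des$type == ty]
    spec_D_group <- equate(spec_D_group, paste("D", conds, sep = "."),
                           to = paste("D", ty, sep = "."))
  }

  # (4) expectancy-equated base model
  des$expected_par <- expected_source_param(des$type, experiment)
  des$unexpected_par <- ifelse(des$expected_par == "d_A", "d_B", "d_A")
  spec_ee <- base
  for (gr in groups) {
    sel <- des$group == gr
    spec_ee <- equate(spec_ee,
                      paste(des$expected_par[sel], des$condition[sel],
                            sep = "."),
                      to = paste("d_expected", gr, sep = "."))
    spec_ee <- equate(spec_ee,
                      paste(des$unexpected_par[sel], des$condition[sel],
                            sep = "."),
                      to = paste("d_unexpected", gr, sep = "."))
  }

  # (5) d_expected = d_unexpected within one group
  spec_d_eq <- lapply(stats::setNames(groups, groups), function(gr) {
    equate(spec_ee, paste(c("d_expected", "d_unexpected"), gr, sep = "."),
           to = paste("d", gr, sep = "."))
  })
  # (6) both d symbols equated across groups
  spec_d_group <- equate(equate(spec_ee,
                                paste("d_expected", groups, sep = "."),
                                to = "d_expected"),
                         paste("d_unexpected", groups, sep = "."),
                         to = "d_unexpected")
  # (7) g equated across types within one group
  spec_g_eq <- lapply(stats::setNames(groups, groups), function(gr) {
    conds <- des$condition[des$group == gr]
    equate(spec_ee, paste("g", conds, sep = "."),
           to = paste("g", gr, sep = "."))
  })

  fit1 <- function(spec) fit_mpt(spec, tables, n_restarts = n_restarts,
                                 seed = seed)
  fits <- list(base = fit1(base),
               D_by_type = fit1(spec_D_type),
               D_by_group = fit1(spec_D_group),
               expectancy_equated = fit1(spec_ee))
  for (gr in groups) {
    fits[[paste0("d_equal.", gr)]] <- fit1(spec_d_eq[[gr]])
  }
  fits$d_by_group <- fit1(spec_d_group)
  for (gr in groups) {
    fits[[paste0("g_equal.", gr)]] <- fit1(spec_g_eq[[gr]])
  }

  cmp <- list(
    list("D_by_type", "item memory equal across types", fits$D_by_type,
         fits$base),
    list("D_by_group", "item memory equal across groups", fits$D_by_group,
         fits$base))
  for (gr in groups) {
    cmp <- c(cmp, list(list(
      paste0("d_expectancy.", gr),
      paste0("source memory equal for expected/unexpected (", gr, ")"),
      fits[[paste0("d_equal.", gr)]], fits$expectancy_equated)))
  }
  cmp <- c(cmp, list(list(
    "d_by_group", "source memory equal across groups",
    fits$d_by_group, fits$expectancy_equated)))
  for (gr in groups) {
    cmp <- c(cmp, list(list(
      paste0("g_by_type.", gr),
      paste0("source guessing equal across types (", gr, ")"),
      fits[[paste0("g_equal.", gr)]], fits$expectancy_equated)))
  }

  comparisons <- do.call(rbind, lapply(cmp, function(ci) {
    cc <- suppressWarnings(
      compare_models(ci[[3]], ci[[4]], labels = c(ci[[1]], "reference")))
    data.frame(test = ci[[1]], label = ci[[2]],
               delta_G2 = cc$delta_G2, delta_df = cc$delta_df,
               p = cc$p_value, w = cc$w,
               decision = if (cc$p_value < alpha) "reject" else "retain")
  }))

  fit_rows <- do.call(rbind, lapply(c("base", "expectancy_equated"),
                                    function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, G2 = f$G2, df = f$df, p = f$p_value,
               N_total = f$N_total)
  }))

  structure(list(fits = fits, comparisons = comparisons,
                 fit_rows = fit_rows, design = des,
                 experiment = experiment, alpha = alpha),
            class = "sm_analysis")
}

#' @export
print.sm_analysis <- function(x, ...) {
  cat("Source-monitoring analysis (", x$experiment, ")\n", sep = "")
  cat("Goodness of fit:\n")
  print(transform(x$fit_rows, G2 = round(G2, 2), p = round(p, 3)),
        row.names = FALSE)
  cat("\nNested comparisons:\n")
  print(transform(x$comparisons, delta_G2 = round(delta_G2, 2),
                  p = round(p, 3), w = round(w, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Guessing-parameter table in the layout of the published tables
#'
#' Extracts the `b` and `g` estimates with 95% confidence intervals per
#' condition from the expectancy-equated reference fit, one column per
#' condition (group x type).
#'
#' @param analysis a [source_memory_analysis()] result.
#' @return A data frame with columns `parameter`, `condition`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
guessing_table <- function(analysis) {
  stopifnot(inherits(analysis, "sm_analysis"))
  fit <- analysis$fits$expectancy_equated
  map <- fit$spec$map
  rows <- map[map$parameter %in% c("b", "g"), ]
  data.frame(parameter = rows$parameter,
             condition = rows$condition,
             estimate = round(unname(fit$estimates[rows$symbol]), 6),
             ci_low = round(unname(fit$ci_low[rows$symbol]), 6),
             ci_high = round(unname(fit$ci_high[rows$symbol]), 6))
}
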