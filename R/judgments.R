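# Contrast-score ANOVAs for 0-100 metamemory judgment scales.  Every
# factor in these designs has exactly two levels, so each within-subject
# effect is a single-df contrast of the four cell means; the contrast-score
# formulation is algebraically identical to the classical repeated-measures
# / mixed ANOVA decomposition and keeps every F a squared t.

#' Per-participant cell means of a 2 x 2 judgment design
#'
#' Averages a judgment measure over trials into the four
#' (item/face type x source/behavior) cells per participant.  Participants
#' with any missing cell are listwise-excluded; the number excluded is
#' recorded in the `n_excluded` attribute.
#'
#' @param trials a data frame from [simulate_experiment()] or read from
#'   its export.
#' @param measure column to average: `"jol"` or `"jos"`.
#' @param phase which rows to use: `"study"` (judgments of learning),
#'   `"postdiction"` or `"belief"`.
#' @return A data frame with columns `participant`, `group` and the four
#'   cell means named `<type>.<source>`, cells ordered type-major.
#' @export
cell_means <- function(trials, measure = c("jos", "jol"),
                       phase = c("study", "postdiction", "belief")) {
  measure <- match.arg(measure)
  phase <- match.arg(phase)
  d <- trials[trials$phase == phase & !trials$buffer &
                !is.na(trials$source) & trials$source != "new", ]
  if (nrow(d) == 0L) stop("no rows for phase '", phase, "'", call. = FALSE)
  eligible <- unique(d$participant)
  d <- d[!is.na(d[[measure]]), ]
  if (nrow(d) == 0L) stop("measure '", measure, "' is entirely missing ",
                          "for phase '", phase, "'", call. = FALSE)
  types <- sort(unique(d$item_type))
  sources <- sort(unique(d$source))
  if (length(types) != 2L || length(sources) != 2L) {
    stop("need a 2 x 2 design (types: ", paste(types, collapse = "/"),
         "; sources: ", paste(sources, collapse = "/"), ")", call. = FALSE)
  }
  cell <- paste(d$item_type, d$source, sep = ".")
  m <- tapply(d[[measure]], list(d$participant, cell), mean)
  grp <- tapply(d$group, d$participant, `[`, 1L)
  cells <- as.vector(outer(sources, types,
                           function(s, t) paste(t, s, sep = ".")))
  m <- m[, cells, drop = FALSE]
  complete <- stats::complete.cases(m)
  out <- data.frame(participant = as.integer(rownames(m)[complete]),
                    group = unname(grp[complete]),
                    m[complete, , drop = FALSE],
                    check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(eligible) - sum(complete)
  attr(out, "cells") <- cells
  out
}

cell_matrix <- function(cm) {
  cells <- attr(cm, "cells")
  if (is.null(cells)) {
    cells <- setdiff(names(cm), c("participant", "group"))
    if (length(cells) != 4L) {
      stop("need exactly four cell-mean columns", call. = FALSE)
    }
  }
  as.matrix(cm[, cells, drop = FALSE])
}

# Contrast scores for a type-major 2x2 cell layout (t1.s1, t1.s2, t2.s1,
# t2.s2): main effect of type, main effect of source, interaction.
contrast_scores <- function(m) {
  cbind(type = (m[, 1] + m[, 2] - m[, 3] - m[, 4]) / 2,
        source = (m[, 1] - m[, 2] + m[, 3] - m[, 4]) / 2,
        interaction = (m[, 1] - m[, 2] - m[, 3] + m[, 4]) / 2)
}

anova_row <- function(effect, F, df1, df2) {
  data.frame(effect = effect, F = F, df1 = df1, df2 = df2,
             p = if (is.na(F)) NA_real_ else f_sf(F, df1, df2),
             eta_p2 = if (is.na(F)) NA_real_ else F * df1 / (F * df1 + df2))
}

# Zero contrast variance: F is 0 when the contrast is identically zero
# (no effect anywhere), undefined (NA) when a nonzero mean has no error
# variance.
one_sample_F <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v)) return(NA_real_)
  if (v == 0) return(if (isTRUE(all.equal(mean(x), 0))) 0 else NA_real_)
  (mean(x) / sqrt(v / n))^2
}

#' Repeated-measures ANOVA for a 2 x 2 within-subject design
#'
#' Each effect (two main effects and the interaction) is a 1-df contrast
#' of the four cell means; its F statistic is the squared one-sample t of
#' the per-participant contrast scores, with `df2 = n - 1`.  Partial eta
#' squared is `F / (F + df2)`.
#'
#' @param cm a [cell_means()] data frame (the `group` column is ignored).
#' @return A data frame of class `"anova_table"` with columns
#'   `effect,F,df1,df2,p,eta_p2`.  Effects with zero contrast variance get
#'   `NA` F (flagged, not an error).
#' @export
rm_anova_2x2 <- function(cm) {
  m <- cell_matrix(cm)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)
  cs <- contrast_scores(m)
  out <- do.call(rbind, lapply(colnames(cs), function(e) {
    anova_row(e, one_sample_F(cs[, e]), 1L, n - 1L)
  }))
  structure(out, class = c("anova_table", "data.frame"))
}

#' Mixed ANOVA for a 2 x 2 within x 2 between design
#'
#' Within-subject effects and their interactions with the between factor
#' are tested on the per-participant contrast scores: the within main
#' effect as the (unweighted) grand mean of the contrast against pooled
#' within-group variance, the interaction with group as the two-sample
#' comparison of contrast scores.  The between main effect is the
#' two-sample comparison of participant means.  All group-involving tests
#' use `df2 = n1 + n2 - 2`; this reproduces the classical Type-III mixed
#' ANOVA for 2-level factors.
#'
#' @param cm a [cell_means()] data frame with a `group` column holding two
#'   groups of at least 2 participants each.
#' @return An `"anova_table"` data frame with the seven effects.
#' @export
mixed_anova_2x2x2 <- function(cm) {
  m <- cell_matrix(cm)
  grp <- factor(cm$group)
  if (nlevels(grp) != 2L) stop("need exactly two groups", call. = FALSE)
  n_g <- table(grp)
  if (any(n_g < 2L)) stop("each group needs at least 2 participants",
                          call. = FALSE)
  n1 <- n_g[[1]]; n2 <- n_g[[2]]
  df2 <- n1 + n2 - 2L
  cs <- contrast_scores(m)

  pooled <- function(x) {
    v1 <- stats::var(x[grp == levels(grp)[1]])
    v2 <- stats::var(x[grp == levels(grp)[2]])
    ((n1 - 1) * v1 + (n2 - 1) * v2) / df2
  }
  grand_F <- function(x) {     # unweighted mean of group means vs 0
    mg <- tapply(x, grp, mean)
    sp2 <- pooled(x)
    est <- mean(mg)
    if (!is.finite(sp2)) return(NA_real_)
    if (sp2 == 0) return(if (isTRUE(all.equal(est, 0))) 0 else NA_real_)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2)) / 2
    (est / se)^2
  }
  between_F <- function(x) {   # two-sample comparison
    mg <- tapply(x, grp, mean)
    sp2 <- pooled(x)
    diff <- mg[[1]] - mg[[2]]
    if (!is.finite(sp2)) return(NA_real_)
    if (sp2 == 0) return(if (isTRUE(all.equal(diff, 0))) 0 else NA_real_)
    (diff / sqrt(sp2 * (1 / n1 + 1 / n2)))^2
  }

  rows <- list(
    anova_row("group", between_F(rowMeans(m)), 1L, df2),
    anova_row("type", grand_F(cs[, "type"]), 1L, df2),
    anova_row("type:group", between_F(cs[, "type"]), 1L, df2),
    anova_row("source", grand_F(cs[, "source"]), 1L, df2),
    anova_row("source:group", between_F(cs[, "source"]), 1L, df2),
    anova_row("type:source", grand_F(cs[, "interaction"]), 1L, df2),
    anova_row("type:source:group", between_F(cs[, "interaction"]), 1L, df2))
  structure(do.call(rbind, rows), class = c("anova_table", "data.frame"))
}

#' Simple interaction effects per group
#'
#' Follow-up to a significant three-way interaction: the type x source
#' interaction contrast tested within each group separately
#' (`df2 = n_group - 1`), at a Bonferroni-corrected level (.025 for two
#' follow-ups) when `bonferroni = TRUE`.
#'
#' @inheritParams mixed_anova_2x2x2
#' @param alpha nominal level before correction.
#' @param bonferroni halve `alpha` across the two groups (the default).
#' @return An `"anova_table"` data frame with one row per group plus a
#'   `decision` column at the (possibly corrected) level.
#' @export
interaction_simple_effects <- function(cm, alpha = 0.05,
                                       bonferroni = TRUE) {
  m <- cell_matrix(cm)
  grp <- factor(cm$group)
  level <- if (bonferroni) alpha / 2 else alpha
  cs <- contrast_scores(m)[, "interaction"]
  rows <- lapply(levels(grp), function(g) {
    x <- cs[grp == g]
    r <- anova_row(paste0("type:source|", g), one_sample_F(x), 1L,
                   length(x) - 1L)
    r$decision <- if (!is.na(r$p) && r$p < level) "reject" else "retain"
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- level
  structure(out, class = c("anova_table", "data.frame"))
}

#' Upper-tail probability of the central F distribution
#'
#' @param F nonnegative statistic.
#' @param df1,df2 positive degrees of freedom.
#' @export
f_sf <- function(F, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1",
                                         call. = FALSE)
  if (any(F < 0)) stop("'F' must be nonnegative", call. = FALSE)
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`; for 1-df effects this is `F / (F + df2)`.
#'
#' @inheritParams f_sf
#' @export
partial_eta_sq <- function(F, df1, df2) {
  F * df1 / (F * df1 + df2)
}

#' @export
print.anova_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$F <- round(y$F, 2)
  y$p <- round(y$p, digits)
  y$eta_p2 <- round(y$eta_p2, 2)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
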