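# Sensitivity power analysis for chi-square (G-squared) tests via the
# noncentral chi-square distribution.

#' Power of a chi-square test at a given noncentrality
#'
#' `P(X > q_crit)` for `X ~ chi-square(df, ncp = lambda)` where `q_crit` is
#' the central critical value at level `alpha`.
#'
#' @param lambda nonnegative noncentrality parameter.
#' @param df positive integer degrees of freedom.
#' @param alpha significance level.
#' @export
chi2_power <- function(lambda, df, alpha = 0.05) {
  if (any(lambda < 0)) stop("'lambda' must be nonnegative", call. = FALSE)
  if (any(df < 1)) stop("'df' must be >= 1", call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df = df)
  stats::pchisq(crit, df = df, ncp = lambda, lower.tail = FALSE)
}

#' Minimal detectable effect size (sensitivity analysis)
#'
#' Solves for the noncentrality `lambda*` at which a chi-square test with
#' `df` degrees of freedom and level `alpha` reaches the requested power,
#' and converts it to the minimal detectable Cohen's
#' `w = sqrt(lambda* / N_total)`.  `lambda*` is found by bisection on the
#' (monotone) noncentral chi-square survival function.
#'
#' @param alpha significance level, in (0, 1).
#' @param power target power `1 - beta`, in (`alpha`, 1).
#' @param N_total total number of responses entering the test.
#' @param df degrees of freedom of the test.
#' @param tol bisection tolerance on `lambda`.
#' @return A list with `w`, `lambda`, `achieved_power`, plus the query.
#' @examples
#' sensitivity_w(alpha = 0.05, power = 0.95, N_total = 120 * 96, df = 4)
#' @export
sensitivity_w <- function(alpha, power, N_total, df, tol = 1e-8) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)",
                                     call. = FALSE)
  if (power <= alpha) {
    stop("requested power must exceed alpha (power at lambda = 0 is alpha)",
         call. = FALSE)
  }
  if (N_total < 1) stop("'N_total' must be positive", call. = FALSE)
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)

  lo <- 0
  hi <- 10
  while (chi2_power(hi, df, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e8) stop("unattainable power", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (chi2_power(mid, df, alpha) < power) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  list(w = sqrt(lambda / N_total), lambda = lambda,
       achieved_power = chi2_power(lambda, df, alpha),
       alpha = alpha, power = power, N_total = N_total, df = df)
}

#' Sensitivity sweep over degrees of freedom
#'
#' The minimal detectable `w` depends on the (often unreported) degrees of
#' freedom of the test; this sweep tabulates it over a df range so a
#' reported sensitivity value can be located instead of asserted.
#'
#' @inheritParams sensitivity_w
#' @param df_values integer vector of df values to sweep.
#' @return A data frame with columns `df`, `lambda`, `w`.
#' @export
sensitivity_sweep <- function(alpha, power, N_total, df_values = 1:24) {
  rows <- lapply(df_values, function(df) {
    s <- sensitivity_w(alpha, power, N_total, df)
    data.frame(df = df, lambda = s$lambda, w = s$w)
  })
  do.call(rbind, rows)
}
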