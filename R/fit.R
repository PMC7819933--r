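#' Model specification for joint multi-tree-set fitting
#'
#' A model spec names the tree sets (conditions) to be fitted jointly and
#' maps every (condition, parameter) pair to a free-symbol name.  By default
#' each condition gets its own five symbols `D.<cond>`, `d_A.<cond>`,
#' `d_B.<cond>`, `b.<cond>`, `g.<cond>`; equality constraints merge symbols
#' ([equate()]) and symbols can be pinned to constants ([fix_par()]).
#'
#' @param tree_sets character vector of condition labels, one tree set each.
#' @return An object of class `"model_spec"`: a list with the symbol `map`
#'   (data frame condition / parameter / symbol) and `fixed` (named numeric
#'   vector of pinned symbols).
#' @examples
#' spec <- model_spec(c("a", "b"))
#' spec <- equate(spec, c("D.a", "D.b"), to = "D")
#' free_symbols(spec)
#' @export
model_spec <- function(tree_sets) {
  tree_sets <- as.character(tree_sets)
  if (anyDuplicated(tree_sets)) {
    stop("tree set labels must be unique", call. = FALSE)
  }
  map <- expand.grid(parameter = PAR_NAMES, condition = tree_sets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  map <- map[, c("condition", "parameter")]
  map$symbol <- paste(map$parameter, map$condition, sep = ".")
  structure(list(tree_sets = tree_sets, map = map, fixed = numeric(0)),
            class = "model_spec")
}

#' @param spec a [model_spec()].
#' @param symbols character vector of (current) symbol names to merge into
#'   one shared free parameter.
#' @param to the name of the merged symbol; defaults to the first element.
#' @rdname model_spec
#' @export
equate <- function(spec, symbols, to = symbols[1]) {
  stopifnot(inherits(spec, "model_spec"))
  missing <- setdiff(symbols, spec$map$symbol)
  if (length(missing)) {
    stop("unknown symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spec$map$symbol[spec$map$symbol %in% symbols] <- to
  if (any(names(spec$fixed) %in% setdiff(symbols, to))) {
    stop("cannot merge a symbol that is fixed to a constant", call. = FALSE)
  }
  spec
}

#' @param symbol a symbol name to pin.
#' @param value the constant in `[0, 1]`.
#' @rdname model_spec
#' @export
fix_par <- function(spec, symbol, value) {
  stopifnot(inherits(spec, "model_spec"))
  if (!symbol %in% spec$map$symbol) {
    stop("unknown symbol: ", symbol, call. = FALSE)
  }
  if (value < 0 || value > 1) stop("fixed value must be in [0, 1]",
                                   call. = FALSE)
  spec$fixed[symbol] <- value
  spec
}

#' @rdname model_spec
#' @export
free_symbols <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  setdiff(unique(spec$map$symbol), names(spec$fixed))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("2HTSM model spec: ", length(x$tree_sets), " tree set(s), ",
      length(free_symbols(x)), " free symbol(s)",
      if (length(x$fixed)) paste0(", ", length(x$fixed), " fixed"), "\n",
      sep = "")
  invisible(x)
}

# Per-condition parameter vectors implied by symbol values.
spec_theta <- function(spec, values) {
  all_vals <- c(values, spec$fixed)
  lapply(stats::setNames(spec$tree_sets, spec$tree_sets), function(cond) {
    rows <- spec$map[spec$map$condition == cond, ]
    v <- all_vals[rows$symbol[match(PAR_NAMES, rows$parameter)]]
    names(v) <- PAR_NAMES
    v
  })
}

joint_loglik <- function(spec, data, values) {
  thetas <- spec_theta(spec, values)
  ll <- 0
  for (cond in spec$tree_sets) {
    p <- category_probabilities(thetas[[cond]])
    ll <- ll + multinom_loglik(unclass(data[[cond]]), p)
    if (identical(ll, -Inf)) return(-Inf)
  }
  ll
}

# Vectorized objective with analytic gradient.  Cells are laid out
# row-major per condition: (A|A, B|A, new|A, A|B, B|B, new|B, A|new,
# B|new, new|new).  All tree-set probabilities are multilinear in the five
# parameters, so the cell derivatives below are exact.
model_objective <- function(spec, data) {
  free <- free_symbols(spec)
  all_syms <- c(free, names(spec$fixed))
  nfree <- length(free)
  vals_fixed <- unname(spec$fixed)
  conds <- spec$tree_sets
  nc <- length(conds)
  idx <- matrix(0L, nc, 5L)
  for (i in seq_len(nc)) {
    rows <- spec$map[spec$map$condition == conds[i], ]
    idx[i, ] <- match(rows$symbol[match(PAR_NAMES, rows$parameter)],
                      all_syms)
  }
  N <- t(vapply(conds,
                function(cn) as.vector(t(unclass(data[[cn]]))),
                numeric(9)))

  cell_probs <- function(V) {
    D <- V[, 1]; dA <- V[, 2]; dB <- V[, 3]; b <- V[, 4]; g <- V[, 5]
    cbind(D * dA + D * (1 - dA) * g + (1 - D) * b * g,
          D * (1 - dA) * (1 - g) + (1 - D) * b * (1 - g),
          (1 - D) * (1 - b),
          D * (1 - dB) * g + (1 - D) * b * g,
          D * dB + D * (1 - dB) * (1 - g) + (1 - D) * b * (1 - g),
          (1 - D) * (1 - b),
          (1 - D) * b * g,
          (1 - D) * b * (1 - g),
          D + (1 - D) * (1 - b))
  }

  values_of <- function(v) {
    vals <- c(pmin(pmax(v, 1e-10), 1 - 1e-10), vals_fixed)
    matrix(vals[idx], nc, 5L)
  }

  ll_of <- function(V) {
    P <- cell_probs(V)
    sum(N * log(pmax(P, 1e-300)))
  }

  # gradient of the log-likelihood with respect to the free symbols on the
  # probability scale
  grad_sym <- function(V) {
    D <- V[, 1]; dA <- V[, 2]; dB <- V[, 3]; b <- V[, 4]; g <- V[, 5]
    P <- cell_probs(V)
    R <- N / pmax(P, 1e-300)               # n / p per cell
    dD <- cbind(dA + (1 - dA) * g - b * g,
                (1 - dA) * (1 - g) - b * (1 - g),
                -(1 - b),
                (1 - dB) * g - b * g,
                dB + (1 - dB) * (1 - g) - b * (1 - g),
                -(1 - b),
                -b * g, -b * (1 - g), b)
    ddA <- cbind(D * (1 - g), -D * (1 - g), 0, 0, 0, 0, 0, 0, 0)
    ddB <- cbind(0, 0, 0, -D * g, D * g, 0, 0, 0, 0)
    db <- cbind((1 - D) * g, (1 - D) * (1 - g), -(1 - D),
                (1 - D) * g, (1 - D) * (1 - g), -(1 - D),
                (1 - D) * g, (1 - D) * (1 - g), -(1 - D))
    dg <- cbind(D * (1 - dA) + (1 - D) * b,
                -(D * (1 - dA) + (1 - D) * b), 0,
                D * (1 - dB) + (1 - D) * b,
                -(D * (1 - dB) + (1 - D) * b), 0,
                (1 - D) * b, -(1 - D) * b, 0)
    per_cell <- cbind(rowSums(R * dD), rowSums(R * ddA), rowSums(R * ddB),
                      rowSums(R * db), rowSums(R * dg))
    acc <- numeric(length(all_syms))
    contrib <- rowsum(as.vector(per_cell), group = as.vector(idx))
    acc[as.integer(rownames(contrib))] <- contrib[, 1]
    acc[seq_len(nfree)]
  }

  list(
    free = free,
    negll = function(z) {
      v <- stats::plogis(z)
      -ll_of(values_of(v))
    },
    grad = function(z) {
      v <- stats::plogis(z)
      -grad_sym(values_of(v)) * v * (1 - v)
    },
    negll_prob = function(v) -ll_of(values_of(v)),
    grad_prob = function(v) -grad_sym(values_of(v)))
}

# Method-of-moments starting values: invert the closed-form hit / false
# alarm / source-attribution relations per tree set, then average over the
# conditions tied to each shared symbol.
moment_start <- function(spec, data) {
  per_cell <- spec$map
  per_cell$value <- NA_real_
  for (cond in spec$tree_sets) {
    n <- unclass(data[[cond]])
    tot <- pmax(rowSums(n), 1)
    pr <- n / tot
    fa <- pr["new", "respA"] + pr["new", "respB"]
    hit <- 1 - (pr["sourceA_old", "respNew"] + pr["sourceB_old", "respNew"]) / 2
    D0 <- clamp01(hit - fa, 0.05, 0.95)
    b0 <- clamp01(fa / max(1 - D0, 0.05), 0.05, 0.95)
    g0 <- clamp01(if (fa > 0) pr["new", "respA"] / fa else 0.5, 0.05, 0.95)
    dA0 <- clamp01((pr["sourceA_old", "respA"] -
                      g0 * (D0 + (1 - D0) * b0)) / (D0 * (1 - g0)),
                   0.05, 0.95)
    dB0 <- clamp01((pr["sourceB_old", "respB"] -
                      (1 - g0) * (D0 + (1 - D0) * b0)) / (D0 * g0),
                   0.05, 0.95)
    est <- c(D = D0, d_A = dA0, d_B = dB0, b = b0, g = g0)
    sel <- per_cell$condition == cond
    per_cell$value[sel] <- est[per_cell$parameter[sel]]
  }
  vapply(split(per_cell$value, per_cell$symbol)[free_symbols(spec)],
         mean, numeric(1))
}

clamp01 <- function(x, lo = 0, hi = 1) {
  if (!is.finite(x)) return(0.5)
  min(max(x, lo), hi)
}

#' Joint maximum-likelihood fit of a 2HTSM model spec
#'
#' Maximizes the joint multinomial log-likelihood of one frequency table per
#' tree set over the free symbols of `spec`, honoring equality constraints
#' and fixed values.  Optimization runs on the logit scale (so estimates
#' stay in the unit interval) with a method-of-moments start plus seeded
#' random restarts; ties among restart winners are broken by highest
#' log-likelihood, then lowest restart index.
#'
#' @param spec a [model_spec()].
#' @param data a named list of [frequency_table()]s covering every tree set
#'   in `spec`.
#' @param n_restarts number of random restarts after the moment-based start.
#' @param seed integer seed for the restart draws (restores the caller's
#'   RNG state on exit).
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return An object of class `"mpt_fit"`: estimates, standard errors and
#'   95% Wald confidence intervals per free symbol, `logL`, `G2`, `df`,
#'   `p_value`, `N_total`, Cohen's `w`, convergence diagnostics, and the
#'   spec/data used.
#' @seealso [compare_models()], [source_memory_analysis()]
#' @export
fit_mpt <- function(spec, data, n_restarts = 10, seed = 1L,
                    reltol = 1e-12) {
  stopifnot(inherits(spec, "model_spec"))
  missing <- setdiff(spec$tree_sets, names(data))
  if (length(missing)) {
    stop("missing frequency table(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- lapply(data[spec$tree_sets], as_freq_table)
  free <- free_symbols(spec)
  n_cat <- 6L * length(spec$tree_sets)
  if (length(free) == 0L) stop("spec has no free symbols", call. = FALSE)
  if (length(free) > n_cat) {
    stop("model not identified: ", length(free), " free symbols but only ",
         n_cat, " independent data categories", call. = FALSE)
  }

  obj <- model_objective(spec, data)

  starts <- list(stats::qlogis(pmin(pmax(moment_start(spec, data),
                                         0.02), 0.98)))
  if (n_restarts > 0) {
    old_rng <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                          envir = globalenv()))
    set.seed(seed)
    for (i in seq_len(n_restarts)) {
      starts[[i + 1L]] <- stats::qlogis(stats::runif(length(free),
                                                     0.05, 0.95))
    }
  }

  best <- NULL
  best_idx <- NA_integer_
  any_conv <- FALSE
  for (i in seq_along(starts)) {
    o <- stats::optim(starts[[i]], obj$negll, gr = obj$grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = reltol))
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value - 1e-12) {
      best <- o
      best_idx <- i
    }
  }

  est <- stats::setNames(stats::plogis(best$par), free)
  logL <- -best$value
  satLL <- sum(vapply(data, saturated_loglik, numeric(1)))
  G2 <- max(2 * (satLL - logL), 0)
  df <- n_cat - length(free)
  N_total <- sum(vapply(data, sum, numeric(1)))

  ci <- wald_ci(spec, data, est, objective = obj)

  structure(list(
    estimates = est,
    se = ci$se, ci_low = ci$low, ci_high = ci$high,
    boundary = ci$boundary, singular_information = ci$singular,
    logL = logL, G2 = G2, df = df,
    p_value = if (df > 0) chi2_sf(G2, df) else NA_real_,
    N_total = N_total, w = cohens_w(G2, N_total),
    converged = any_conv, n_restarts_used = length(starts) - 1L,
    best_start = best_idx, spec = spec, data = data),
    class = "mpt_fit")
}

# Wald intervals from the observed information over the free symbols on the
# probability scale.  Boundary estimates give one-sided/degenerate
# intervals; a singular information matrix is flagged and yields maximally
# wide clipped intervals rather than an error.
wald_ci <- function(spec, data, est, level = 0.95, objective = NULL) {
  free <- names(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  boundary <- est < 1e-6 | est > 1 - 1e-6
  if (is.null(objective)) objective <- model_objective(spec, data)
  se <- rep(NA_real_, length(free))
  singular <- FALSE
  H <- try(stats::optimHess(unname(est), objective$negll_prob,
                            gr = objective$grad_prob), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V)))) {
      d <- diag(V)
      se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
      singular <- any(d <= 0)
    } else {
      singular <- TRUE
    }
  } else {
    singular <- TRUE
  }
  se[!is.finite(se)] <- NA_real_
  low <- ifelse(is.na(se), 0, pmin(pmax(est - z * se, 0), 1))
  high <- ifelse(is.na(se), 1, pmin(pmax(est + z * se, 0), 1))
  low[boundary & est < 0.5] <- 0
  high[boundary & est > 0.5] <- 1
  list(se = stats::setNames(se, free),
       low = stats::setNames(low, free),
       high = stats::setNames(high, free),
       boundary = stats::setNames(boundary, free),
       singular = singular)
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("2HTSM joint fit: ", length(x$spec$tree_sets), " tree set(s), ",
      length(x$estimates), " free symbol(s)\n", sep = "")
  cat(sprintf("G2(%d) = %.2f, p = %.3f, N = %d, w = %.2f%s\n",
              x$df, x$G2, x$p_value, x$N_total, x$w,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  tab <- data.frame(estimate = round(x$estimates, digits),
                    ci_low = round(x$ci_low, digits),
                    ci_high = round(x$ci_high, digits))
  print(tab, ...)
  invisible(x)
}

#' @export
confint.mpt_fit <- function(object, parm, level = 0.95, ...) {
  ci <- wald_ci(object$spec, object$data, object$estimates, level = level)
  out <- cbind(ci$low, ci$high)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$logL, df = length(object$estimates), class = "logLik")
}

#' Export a fit as a flat data frame
#'
#' One row per free symbol with the estimate and 95% CI plus the shared fit
#' statistics, ready for delimited-text export (estimates to 6 decimals,
#' p to 3, w to 2).
#'
#' @param fit an [fit_mpt()] result.
#' @return A data frame.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  data.frame(symbol = names(fit$estimates),
             estimate = round(unname(fit$estimates), 6),
             ci_low = round(unname(fit$ci_low), 6),
             ci_high = round(unname(fit$ci_high), 6),
             G2 = round(fit$G2, 6), df = fit$df,
             p = round(fit$p_value, 3),
             N_total = fit$N_total, w = round(fit$w, 2),
             converged = fit$converged)
}

#' Upper-tail probability of the central chi-square distribution
#'
#' The p-value attached to every G-squared and delta-G-squared statistic.
#'
#' @param x nonnegative statistic.
#' @param df positive integer degrees of freedom.
#' @return `P(X > x)` for `X ~ chi-square(df)`.
#' @examples
#' chi2_sf(3.71, 4)
#' @export
chi2_sf <- function(x, df) {
  if (any(df < 1)) stop("'df' must be >= 1", call. = FALSE)
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Cohen's w effect size for chi-square tests
#'
#' `sqrt(G2 / N)` where `N` is the total number of test responses
#' (participants times test trials).
#'
#' @param G2 nonnegative chi-square / G-squared statistic.
#' @param N_total positive total number of responses.
#' @examples
#' cohens_w(124.37, 120 * 96)
#' @export
cohens_w <- function(G2, N_total) {
  if (any(N_total <= 0)) stop("'N_total' must be positive", call. = FALSE)
  if (any(G2 < 0)) stop("'G2' must be nonnegative", call. = FALSE)
  sqrt(G2 / N_total)
}
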