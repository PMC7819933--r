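# Fixed enumerations: item classes (tree roots) and test responses, in the
# order used for every table in the package.  Stable order matters for
# serialization, so these are constants rather than arguments.
ITEM_CLASSES <- c("sourceA_old", "sourceB_old", "new")
RESPONSES <- c("respA", "respB", "respNew")
PAR_NAMES <- c("D", "d_A", "d_B", "b", "g")

#' Parameter vector of the two-high-threshold source-monitoring model
#'
#' Bundles the five probabilities of the 2HTSM: `D`, the probability of
#' detecting an old item as old (and, under the identifiability restriction
#' used throughout, of detecting a new item as new); `d_A` and `d_B`, the
#' conditional probabilities of remembering the source of a detected
#' Source-A or Source-B item; `b`, the conditional probability of guessing
#' "old" for an undetected item; and `g`, the conditional probability of
#' guessing Source A when source memory fails.
#'
#' A single `D` applies to Source-A items, Source-B items and new items.
#' This is the standard restriction that makes the model identifiable from
#' one 3x3 frequency table per condition.
#'
#' @param D,d_A,d_B,b,g probabilities in `[0, 1]`.
#' @return A named numeric vector of class `"htsm_par"`.
#' @examples
#' theta <- htsm_par(D = 0.7, d_A = 0.5, d_B = 0.5, b = 0.4, g = 0.6)
#' category_probabilities(theta)
#' @export
htsm_par <- function(D, d_A, d_B, b, g) {
  theta <- c(D = D, d_A = d_A, d_B = d_B, b = b, g = g)
  check_unit_interval(theta)
  structure(theta, class = "htsm_par")
}

check_unit_interval <- function(theta) {
  for (nm in names(theta)) {
    x <- theta[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1], got ",
           format(x), call. = FALSE)
    }
  }
  invisible(theta)
}

#' @export
print.htsm_par <- function(x, digits = 4, ...) {
  cat("2HTSM parameter vector\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Category probabilities of the 2HTSM trees
#'
#' Computes the 3x3 table of response probabilities (item class x response)
#' implied by a parameter vector.  Each row of the result is the multinomial
#' distribution of test responses for one item class and sums to 1.
#'
#' For Source-A items:
#' \deqn{P(A|A) = D d_A + D(1-d_A)g + (1-D)bg}
#' \deqn{P(B|A) = D(1-d_A)(1-g) + (1-D)b(1-g)}
#' \deqn{P(new|A) = (1-D)(1-b)}
#' Source-B items are symmetric with `d_B` and the source-guessing
#' probabilities `g` and `1-g` exchanged.  For new items the detect state
#' leads to a correct "new" response:
#' \deqn{P(A|new) = (1-D)bg, \quad P(new|new) = D + (1-D)(1-b).}
#'
#' @param theta an [htsm_par()] vector (or a named numeric vector with the
#'   same five elements).
#' @return A 3x3 numeric matrix with rows `sourceA_old`, `sourceB_old`,
#'   `new` and columns `respA`, `respB`, `respNew`.
#' @export
category_probabilities <- function(theta) {
  theta <- as_htsm_par(theta)
  D <- theta[["D"]]; dA <- theta[["d_A"]]; dB <- theta[["d_B"]]
  b <- theta[["b"]]; g <- theta[["g"]]
  p <- matrix(0, 3, 3, dimnames = list(ITEM_CLASSES, RESPONSES))
  p["sourceA_old", ] <- c(
    D * dA + D * (1 - dA) * g + (1 - D) * b * g,
    D * (1 - dA) * (1 - g) + (1 - D) * b * (1 - g),
    (1 - D) * (1 - b))
  p["sourceB_old", ] <- c(
    D * (1 - dB) * g + (1 - D) * b * g,
    D * dB + D * (1 - dB) * (1 - g) + (1 - D) * b * (1 - g),
    (1 - D) * (1 - b))
  p["new", ] <- c(
    (1 - D) * b * g,
    (1 - D) * b * (1 - g),
    D + (1 - D) * (1 - b))
  p
}

as_htsm_par <- function(theta) {
  if (inherits(theta, "htsm_par")) return(theta)
  if (is.numeric(theta) && all(PAR_NAMES %in% names(theta))) {
    return(htsm_par(theta[["D"]], theta[["d_A"]], theta[["d_B"]],
                    theta[["b"]], theta[["g"]]))
  }
  stop("'theta' must be an htsm_par vector or a named numeric vector with ",
       "elements D, d_A, d_B, b, g", call. = FALSE)
}

#' Observed response-frequency table for one condition
#'
#' A 3x3 table of nonnegative integer counts, item class (Source-A old,
#' Source-B old, new) by response (Source A, Source B, new), for one tree
#' set (one condition, e.g. one item type within one judgment group).
#'
#' @param counts a 3x3 matrix-like object of nonnegative counts.  Rows are
#'   taken in the order Source-A old, Source-B old, new; columns in the
#'   order response A, response B, response new.
#' @param label a condition identifier.
#' @return A matrix of class `"freq_table"` with a `label` attribute.
#' @examples
#' frequency_table(rbind(c(60, 25, 15), c(25, 60, 15), c(20, 20, 60)),
#'                 label = "example")
#' @export
frequency_table <- function(counts, label = "") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("'counts' must be a 3x3 table of item class x response",
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  counts <- round(counts)
  dimnames(counts) <- list(ITEM_CLASSES, RESPONSES)
  structure(counts, class = "freq_table", label = as.character(label))
}

#' @export
print.freq_table <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Response frequencies", if (nzchar(lab)) paste0(" [", lab, "]"), "\n",
      sep = "")
  print(matrix(x, 3, 3, dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Multinomial log-likelihood of a frequency table
#'
#' Sum over cells of `count * log(probability)` under the category
#' probabilities implied by `theta`, with the convention that cells with a
#' zero count contribute 0.  If any cell has a positive count but zero
#' model probability the log-likelihood is `-Inf`.
#'
#' @param freqs a [frequency_table()].
#' @param theta an [htsm_par()] vector.
#' @return A single number (possibly `-Inf`).
#' @export
log_likelihood <- function(freqs, theta) {
  freqs <- as_freq_table(freqs)
  p <- category_probabilities(theta)
  multinom_loglik(freqs, p)
}

multinom_loglik <- function(n, p) {
  pos <- n > 0
  if (any(pos & p == 0)) return(-Inf)
  sum(n[pos] * log(p[pos]))
}

as_freq_table <- function(freqs) {
  if (inherits(freqs, "freq_table")) return(freqs)
  frequency_table(freqs)
}

# Log-likelihood of the saturated model: each row at its observed
# proportions.  Rows with a zero total contribute 0.
saturated_loglik <- function(freqs) {
  n <- unclass(freqs)
  tot <- rowSums(n)
  ll <- 0
  for (i in seq_len(nrow(n))) {
    if (tot[i] == 0) next
    pos <- n[i, ] > 0
    ll <- ll + sum(n[i, pos] * log(n[i, pos] / tot[i]))
  }
  ll
}

#' Likelihood-ratio goodness-of-fit statistic for one table
#'
#' \eqn{G^2 = 2 \sum n \log(n / (N_{row} p))} over cells, with
#' \eqn{0 \log 0 := 0}.  Equals twice the gap between the saturated and the
#' model log-likelihood; zero exactly when the model probabilities equal the
#' observed row proportions.  A positive count on a zero-probability cell
#' yields `Inf` (flagged, not an error).
#'
#' @inheritParams log_likelihood
#' @return A nonnegative number, `Inf` if the model assigns probability zero
#'   to an observed cell.
#' @export
g_squared_stat <- function(freqs, theta) {
  freqs <- as_freq_table(freqs)
  ll <- log_likelihood(freqs, theta)
  if (identical(ll, -Inf)) return(Inf)
  max(2 * (saturated_loglik(freqs) - ll), 0)
}

#' Read / write frequency tables as delimited text
#'
#' The on-disk format is long: columns `condition,item_class,response,count`,
#' comma-separated with a header.  One table per condition label.
#'
#' @param file path to a delimited text file.
#' @return `read_frequency_tables()` returns a named list of
#'   [frequency_table()] objects; `write_frequency_tables()` returns `file`
#'   invisibly.
#' @export
read_frequency_tables <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("condition", "item_class", "response", "count")
  if (!all(need %in% names(df))) {
    stop("file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$response), RESPONSES)
  if (length(bad)) {
    stop("unknown response code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$item_class), ITEM_CLASSES)
  if (length(bad)) {
    stop("unknown item class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$condition), function(d) {
    m <- matrix(0, 3, 3, dimnames = list(ITEM_CLASSES, RESPONSES))
    for (i in seq_len(nrow(d))) {
      m[d$item_class[i], d$response[i]] <- m[d$item_class[i], d$response[i]] +
        d$count[i]
    }
    frequency_table(m, label = d$condition[1])
  })
  out[unique(df$condition)]
}

#' @param tables a named list of [frequency_table()] objects.
#' @rdname read_frequency_tables
#' @export
write_frequency_tables <- function(tables, file) {
  rows <- lapply(names(tables), function(nm) {
    m <- unclass(tables[[nm]])
    data.frame(condition = nm,
               item_class = rep(ITEM_CLASSES, each = 3),
               response = rep(RESPONSES, times = 3),
               count = as.vector(t(m)))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}
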