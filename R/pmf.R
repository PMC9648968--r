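#' Probability mass function containers
#'
#' Model distributions are stored as truncated probability vectors over the
#' integers 0..K. Two kinds are distinguished: `"count"` for molecule-number
#' distributions (mature mRNA, bound Pol II) and `"signal"` for discretized
#' fluorescence-bin distributions (bin 0 = zero signal, bin i >= 1 = signal in
#' (i-1, i]). Convolution and likelihood code refuses to mix the two kinds.
#'
#' @param probs Numeric vector of probabilities for values 0..K.
#' @param kind `"count"` or `"signal"`.
#' @param eps Tail-mass bound the truncation was chosen for.
#' @param params Optional parameter object recorded for provenance.
#' @return An object of class `burst_pmf`.
#' @export
burst_pmf <- function(probs, kind = c("count", "signal"), eps = 1e-8,
                      params = NULL) {
  kind <- match.arg(kind)
  if (any(!is.finite(probs)) || any(probs < -1e-12)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (s > 1 + 1e-8) stop("probabilities sum to more than 1", call. = FALSE)
  structure(list(probs = probs, kind = kind, K = length(probs) - 1L,
                 tail_mass_bound = max(0, 1 - s), eps = eps, params = params),
            class = "burst_pmf")
}

#' @export
print.burst_pmf <- function(x, ...) {
  cat(sprintf("<burst_pmf> kind = %s, support 0..%d, mass %.8f, mean %.4f\n",
              x$kind, x$K, sum(x$probs), pmf_mean(x)))
  invisible(x)
}

#' Mean of a truncated PMF
#' @param pmf A [burst_pmf].
#' @return The mean of the stored (truncated) distribution.
#' @export
pmf_mean <- function(pmf) {
  stopifnot(inherits(pmf, "burst_pmf"))
  sum(pmf$probs * (seq_along(pmf$probs) - 1))
}

#' Variance of a truncated PMF
#' @param pmf A [burst_pmf].
#' @return The variance of the stored distribution.
#' @export
pmf_var <- function(pmf) {
  stopifnot(inherits(pmf, "burst_pmf"))
  x <- seq_along(pmf$probs) - 1
  m <- sum(pmf$probs * x)
  sum(pmf$probs * (x - m)^2)
}

#' Fano factor (variance over mean) of a distribution
#'
#' Equals 1 for a Poisson distribution; super-Poissonian values indicate
#' bursty transcription.
#'
#' @param pmf A [burst_pmf].
#' @return variance / mean.
#' @export
fano_factor <- function(pmf) {
  m <- pmf_mean(pmf)
  if (m <= 0) stop("Fano factor undefined: distribution has zero mean", call. = FALSE)
  pmf_var(pmf) / m
}

#' Discrete convolution of two PMFs
#'
#' The distribution of the sum of two independent variables; used to model
#' cells carrying two independently transcribing gene copies, whose total
#' molecule number (or signal) distribution is the single-copy distribution
#' convolved with itself.
#'
#' @param p,q [burst_pmf] objects of the same kind.
#' @return A [burst_pmf] over 0..(Kp + Kq); total mass and means add exactly.
#' @examples
#' u <- burst_pmf(c(0.5, 0.5))
#' convolve_pmf(u, u)$probs  # 0.25 0.50 0.25
#' @export
convolve_pmf <- function(p, q) {
  stopifnot(inherits(p, "burst_pmf"), inherits(q, "burst_pmf"))
  if (p$kind != q$kind) {
    stop("cannot convolve PMFs with different bin conventions (",
         p$kind, " vs ", q$kind, ")", call. = FALSE)
  }
  pr <- stats::convolve(p$probs, rev(q$probs), type = "open")
  pr[pr < 0] <- 0                      # clip fft round-off
  if (sum(pr) > 1) pr <- pr / sum(pr)  # round-off above exact mass sum(p)*sum(q)
  burst_pmf(pr, kind = p$kind, eps = max(p$eps, q$eps))
}

#' Write / read a PMF as a two-column CSV
#'
#' Columns `index` (0-based support) and `probability`.
#'
#' @param pmf A [burst_pmf].
#' @param path File path.
#' @return `write_pmf_csv` returns `path` invisibly; `read_pmf_csv` returns a
#'   [burst_pmf].
#' @param kind Bin convention to tag the PMF read back with.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "burst_pmf"))
  utils::write.csv(
    data.frame(index = seq_along(pmf$probs) - 1L, probability = pmf$probs),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf_csv
#' @export
read_pmf_csv <- function(path, kind = c("count", "signal")) {
  df <- utils::read.csv(path)
  if (!all(c("index", "probability") %in% names(df))) {
    stop("PMF CSV must have columns index, probability", call. = FALSE)
  }
  df <- df[order(df$index), ]
  if (!identical(as.integer(df$index), seq_len(nrow(df)) - 1L)) {
    stop("PMF CSV index must be contiguous from 0", call. = FALSE)
  }
  burst_pmf(df$probability, kind = match.arg(kind))
}

#' Serialize a PMF to a JSON envelope
#'
#' Carries the probabilities together with truncation, tail bound and the
#' generating parameters (if recorded).
#'
#' @param pmf A [burst_pmf].
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
pmf_to_json <- function(pmf, path = NULL) {
  stopifnot(inherits(pmf, "burst_pmf"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  obj <- list(kind = pmf$kind, K = pmf$K, eps = pmf$eps,
              tail_mass_bound = pmf$tail_mass_bound,
              params = if (is.null(pmf$params)) NULL else strip(pmf$params),
              probs = pmf$probs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# total variation distance between two discrete distributions on 0..K
# (vectors padded to common length); used throughout the test oracles
#' Total variation distance between two PMFs or probability vectors
#' @param p,q [burst_pmf] objects or bare probability vectors.
#' @return `0.5 * sum(|p - q|)` after padding to a common support.
#' @export
total_variation <- function(p, q) {
  if (inherits(p, "burst_pmf")) p <- p$probs
  if (inherits(q, "burst_pmf")) q <- q$probs
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}
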