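#' Normalized autocorrelation function of intensity traces
#'
#' Per trace: mean-subtracted autocovariance (biased estimator, divided by
#' the trace length) normalized by the trace variance, so the value at lag 0
#' is exactly 1 and the curve is invariant to gain and offset of the signal
#' -- which is what makes ACFs from live-cell traces with cell-to-cell
#' intensity variation comparable. Curves are averaged across traces.
#'
#' @param traces A list of numeric vectors (or one vector), sampled at a
#'   common interval `dt`.
#' @param max_lag Largest lag, in minutes.
#' @param dt Sampling interval in minutes.
#' @return An object of class `acf_curve`: `lags` (min), `values`,
#'   `n_traces`. Zero-variance traces are excluded with a warning; if all
#'   are excluded, an error.
#' @examples
#' tr <- simulate_intensity_trace(nascent_model(rate_params(1, 1, 20)),
#'                                duration = 60, dt = 0.1, seed = 1)
#' a <- normalized_acf(tr, max_lag = 5, dt = 0.1)
#' a$values[1]  # exactly 1
#' @export
normalized_acf <- function(traces, max_lag, dt) {
  if (is.numeric(traces)) traces <- list(traces)
  n_lag <- floor(max_lag / dt)
  lens <- vapply(traces, length, integer(1))
  if (any(lens <= 2 * n_lag)) {
    stop("each trace must be longer than 2 * max_lag / dt points", call. = FALSE)
  }
  ok <- vapply(traces, function(x) stats::var(x) > 0, logical(1))
  if (!any(ok)) stop("all traces have zero variance", call. = FALSE)
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance trace(s) excluded", call. = FALSE)
  }
  curves <- vapply(traces[ok], function(x) {
    as.numeric(stats::acf(x, lag.max = n_lag, plot = FALSE,
                          demean = TRUE)$acf)
  }, numeric(n_lag + 1L))
  vals <- if (is.matrix(curves)) rowMeans(curves) else curves
  vals[1] <- 1  # c(0)/c(0) is exactly 1; guard against float division wobble
  structure(list(lags = (0:n_lag) * dt, values = vals, n_traces = sum(ok)),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("<acf_curve> %d traces, lags 0..%g min (%d points)\n",
              x$n_traces, max(x$lags), length(x$lags)))
  invisible(x)
}

#' Sum of squared residuals between two ACF curves
#'
#' The reference curve is linearly interpolated onto the model curve's lags;
#' the result is the sum over those lags of the squared difference -- the
#' score used to compare simulated transcription kinetics against a
#' live-cell reference.
#'
#' @param model An `acf_curve` (or list with `lags`, `values`).
#' @param reference An `acf_curve` or a data.frame with columns `lag` (min)
#'   and `acf` (e.g. read from a two-column CSV).
#' @return Non-negative scalar; zero iff the curves coincide on the model
#'   lags.
#' @export
acf_ssr <- function(model, reference) {
  ml <- model$lags; mv <- model$values
  if (is.data.frame(reference)) {
    if (!all(c("lag", "acf") %in% names(reference))) {
      stop("reference data.frame needs columns lag, acf", call. = FALSE)
    }
    rl <- reference$lag; rv <- reference$acf
  } else {
    rl <- reference$lags; rv <- reference$values
  }
  if (min(ml) < min(rl) - 1e-9 || max(ml) > max(rl) + 1e-9) {
    stop("reference lags do not cover the model lags; cannot interpolate",
         call. = FALSE)
  }
  ref_on_model <- stats::approx(rl, rv, xout = ml)$y
  sum((mv - ref_on_model)^2)
}
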