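#' Fuse the lowest k bins of a model PMF and dataset
#'
#' Curation for transcription-site misidentification noise: all values below
#' `k` are merged into one fused bin whose model probability is the sum of
#' the first `k` bin probabilities. `k = 1` is the identity (uncurated
#' data). On the returned objects the fused bin has index 0 and original bin
#' `i >= k` has index `i - (k - 1)`.
#'
#' @param pmf A [burst_pmf].
#' @param data Integer vector of observed values on the same bin convention.
#' @param k Number of low bins to fuse (>= 1).
#' @return A list with elements `pmf` (transformed [burst_pmf]), `values`
#'   (transformed data) and `k`.
#' @examples
#' p <- burst_pmf(c(0.1, 0.1, 0.1, 0.1, 0.6), "signal")
#' curate_fusion(p, c(0, 1, 2, 3, 4), k = 4)$pmf$probs  # 0.4 0.6
#' @export
curate_fusion <- function(pmf, data, k) {
  stopifnot(inherits(pmf, "burst_pmf"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1L) {
    return(list(pmf = pmf, values = as.integer(data), k = 1L))
  }
  if (k > length(pmf$probs)) {
    stop("k = ", k, " exceeds the model support (0..", pmf$K, ")", call. = FALSE)
  }
  fused <- c(sum(pmf$probs[seq_len(k)]), pmf$probs[-seq_len(k)])
  vals <- as.integer(ifelse(data < k, 0L, data - (k - 1L)))
  list(pmf = burst_pmf(fused, kind = pmf$kind, eps = pmf$eps, params = pmf$params),
       values = vals, k = k)
}

#' Reject the lowest k bins and condition the model on the rest
#'
#' Curation that drops all cells with values below `k` and renormalizes the
#' model over the surviving bins, i.e. fits the conditional distribution
#' given a value of at least `k`. On the returned objects original bin
#' `i >= k` has index `i - k`.
#'
#' @param pmf A [burst_pmf].
#' @param data Integer vector of observed values.
#' @param k Number of low bins to reject (>= 1).
#' @return A list with elements `pmf` (conditional [burst_pmf]), `values`
#'   (surviving, shifted data) and `k`.
#' @examples
#' p <- burst_pmf(c(0.25, 0.25, 0.5), "signal")
#' curate_rejection(p, c(0, 1, 2, 2), k = 2)$pmf$probs  # 1
#' @export
curate_rejection <- function(pmf, data, k) {
  stopifnot(inherits(pmf, "burst_pmf"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > pmf$K) {
    stop("k = ", k, " leaves no model support", call. = FALSE)
  }
  keep <- data >= k
  if (!any(keep)) stop("rejection with k = ", k, " drops every cell", call. = FALSE)
  surv <- pmf$probs[-seq_len(k)]
  total <- sum(surv)
  if (total <= 0) stop("model places no mass on bins >= ", k, call. = FALSE)
  list(pmf = burst_pmf(surv / total, kind = pmf$kind, eps = pmf$eps,
                       params = pmf$params),
       values = as.integer(data[keep] - k), k = k)
}

# model distribution for a dataset at given rates: telegraph (mature) or
# binned trapezoidal signal (nascent), self-convolved for independent
# two-copy cells, rate-doubled for synchronized copies
.model_pmf <- function(params, kind, copy_mode, scale, max_obs, eps = 1e-8) {
  two_indep <- copy_mode == "two-copy-independent"
  if (copy_mode == "two-copy-synchronized") {
    params <- rate_params(params$sigma_on, params$sigma_off, 2 * params$rho)
  }
  min_K <- if (two_indep) ceiling(max_obs / 2) + 1L else max_obs
  base <- if (kind == "mature-counts") {
    telegraph_pmf(mature_model(params, d = scale$d), eps = eps, min_K = min_K)
  } else {
    signal_bin_pmf(nascent_model(params, tau = scale$tau,
                                 geometry = scale$geometry),
                   eps = eps, min_K = min_K)
  }
  if (two_indep) convolve_pmf(base, base) else base
}

#' Negative log-likelihood of a dataset under the telegraph family
#'
#' Computes `-sum_j log P(value_j; theta)` where the per-cell distribution is
#' the telegraph steady state ([telegraph_pmf()]) for mature counts or the
#' binned signal distribution ([signal_bin_pmf()]) for nascent bins, adjusted
#' for the dataset's copy mode and curation. Model probabilities are floored
#' at `p_floor` so the objective stays finite; observations that hit the
#' floor indicate gross data-model mismatch and raise a warning (optional).
#'
#' @param data An [observed_dataset].
#' @param params A [rate_params] object.
#' @param scale A [scale_cfg] supplying `d` (mature) or `tau` and the gene
#'   geometry (nascent).
#' @param eps PMF tail tolerance passed to the model solvers.
#' @param p_floor Probability floor (default 1e-15).
#' @param warn Warn when an observation's model probability hits the floor.
#' @return The negative log-likelihood (finite scalar).
#' @examples
#' d <- observed_dataset(c(0, 1), kind = "mature-counts")
#' # a model with P(0) = P(1) = 0.5 would give 2 log 2
#' @export
negative_log_likelihood <- function(data, params, scale = scale_cfg(),
                                    eps = 1e-8, p_floor = 1e-15, warn = TRUE) {
  stopifnot(inherits(data, "observed_dataset"), inherits(params, "rate_params"),
            inherits(scale, "scale_cfg"))
  v <- data$hist$value
  n <- data$hist$count
  pmf <- .model_pmf(params, data$kind, data$copy_mode, scale,
                    max_obs = max(v), eps = eps)
  if (data$curation == "fusion") {
    cur <- curate_fusion(pmf, v, data$curation_k)
    pmf <- cur$pmf
    v <- cur$values
    if (any(v == 0L)) {  # merge multiplicities mapped onto the fused bin
      n <- c(sum(n[v == 0L]), n[v != 0L])
      v <- c(0L, v[v != 0L])
    }
  } else if (data$curation == "rejection") {
    keep <- v >= data$curation_k
    if (!any(keep)) stop("rejection with k = ", data$curation_k,
                         " drops every cell", call. = FALSE)
    cur <- curate_rejection(pmf, v[keep], data$curation_k)
    pmf <- cur$pmf
    v <- cur$values
    n <- n[keep]
  }
  p <- rep(p_floor, length(v))
  inside <- v <= pmf$K
  p[inside] <- pmax(pmf$probs[v[inside] + 1L], p_floor)
  if (warn && any(p <= p_floor)) {
    warning("some observations have model probability at the floor (",
            format(p_floor), "); data and model may be incompatible",
            call. = FALSE)
  }
  -sum(n * log(p))
}
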