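#' Steady-state mature mRNA distribution of the telegraph model
#'
#' Solves the chemical master equation of the two-state telegraph model
#' (promoter switching at rates `sigma_on`/`sigma_off`, initiation at `rho`
#' while ON, first-order degradation at `d`) by finite state projection:
#' the state space (promoter state, mRNA number 0..K) is truncated at K and
#' the stationary distribution of the truncated generator is obtained from a
#' sparse linear solve. K starts at mean + 10 sd (closed-form telegraph
#' moments) and doubles until the captured mass is at least `1 - eps`.
#'
#' @param spec A [mature_model].
#' @param eps Tail-mass tolerance (default 1e-8).
#' @param min_K Optional lower bound on the truncation (used by the
#'   likelihood code so observed counts are always inside the support).
#' @param max_K Hard cap on the truncation (default 50000).
#' @return A [burst_pmf] of kind `"count"`.
#' @examples
#' p <- telegraph_pmf(mature_model(rate_params(1, 0, 5), d = 1))
#' p$probs[1]  # exp(-5): always-ON limit is Poisson(rho/d)
#' @export
telegraph_pmf <- function(spec, eps = 1e-8, min_K = 0L, max_K = 50000L) {
  stopifnot(inherits(spec, "mature_model"))
  if (eps <= 0 || eps >= 1) stop("eps must be in (0, 1)", call. = FALSE)
  r <- spec$rates
  d <- spec$d
  s_on <- r$sigma_on; s_off <- r$sigma_off; rho <- r$rho

  # degenerate limits with an atom at zero
  if (rho == 0 || s_on == 0) {
    probs <- c(1, rep(0, min_K))
    return(burst_pmf(probs, "count", eps = eps, params = spec))
  }
  if (s_on + s_off == 0) {
    stop("invalid parameters: sigma_on + sigma_off must be positive", call. = FALSE)
  }
  if (s_off == 0) {
    # promoter permanently ON: exact Poisson(rho / d) limit
    lam <- rho / d
    K <- max(min_K, stats::qpois(1 - eps / 10, lam) + 3L)
    return(burst_pmf(stats::dpois(0:K, lam), "count", eps = eps, params = spec))
  }

  f_on <- s_on / (s_on + s_off)
  mn <- rho * f_on / d
  fano <- 1 + rho * s_off / ((s_on + s_off) * (d + s_on + s_off))
  K <- max(10L, min_K, ceiling(mn + 8 * sqrt(mn * fano)))

  repeat {
    if (K > max_K) {
      stop("FSP truncation exceeded hard cap max_K = ", max_K, call. = FALSE)
    }
    pr <- cpp_telegraph_stationary(s_on, s_off, rho, d, K)
    # the truncated chain renormalizes onto 0..K; accept only if the mass
    # pushed against the boundary is negligible
    if (sum(pr[(K - 1L):(K + 1L)]) < eps) break
    K <- 2L * K
  }
  pr <- .trim_pmf_tail(pr, eps, min_len = min_K + 1L)
  burst_pmf(pr, "count", eps = eps, params = spec)
}

# drop the all-but-negligible upper tail, keeping mass >= 1 - eps
.trim_pmf_tail <- function(pr, eps, min_len = 1L) {
  keep <- max(min_len, which(cumsum(pr) >= 1 - eps)[1], na.rm = TRUE)
  if (is.na(keep) || keep >= length(pr)) pr else pr[seq_len(keep)]
}
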