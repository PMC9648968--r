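#' Steady-state distribution of gene-bound Pol II (delay telegraph model)
#'
#' In the delay telegraph model each initiated polymerase resides on the gene
#' for exactly `tau` minutes, so in steady state the number of bound Pol II
#' equals the number of initiation events of the telegraph-gated Poisson
#' process in a window of length `tau`, started from the stationary promoter
#' distribution. The transient counting process over (promoter state,
#' initiation count) is integrated by uniformization (randomization), which is
#' exact up to the Poisson-tail cutoff and keeps all iterates non-negative.
#' The mean equals `rho * tau * fON` analytically.
#'
#' @param spec A [nascent_model].
#' @param eps Tail-mass tolerance (default 1e-8).
#' @param min_K Optional lower bound on the truncation.
#' @param max_K Hard cap on the truncation (default 50000).
#' @return A [burst_pmf] of kind `"count"` over the Pol II number k.
#' @examples
#' p <- delay_polii_pmf(nascent_model(rate_params(1, 0, 4), tau = 0.5))
#' p$probs[1]  # exp(-2): always-ON limit is Poisson(rho * tau)
#' @export
delay_polii_pmf <- function(spec, eps = 1e-8, min_K = 0L, max_K = 50000L) {
  stopifnot(inherits(spec, "nascent_model"))
  if (eps <= 0 || eps >= 1) stop("eps must be in (0, 1)", call. = FALSE)
  r <- spec$rates
  s_on <- r$sigma_on; s_off <- r$sigma_off; rho <- r$rho; tau <- spec$tau

  if (rho == 0 || s_on == 0) {
    return(burst_pmf(c(1, rep(0, min_K)), "count", eps = eps, params = spec))
  }
  if (s_on + s_off == 0) {
    stop("invalid parameters: sigma_on + sigma_off must be positive", call. = FALSE)
  }

  # counts are bounded above by a Poisson(rho * tau) (promoter always ON)
  K <- max(5L, min_K, stats::qpois(1 - eps / 10, rho * tau) + 5L)
  repeat {
    if (K > max_K) {
      stop("FSP truncation exceeded hard cap max_K = ", max_K, call. = FALSE)
    }
    pr <- cpp_delay_counting(s_on, s_off, rho, tau, K, eps)
    if (1 - sum(pr) < eps) break
    K <- 2L * K
  }
  pr <- .trim_pmf_tail(pr, eps, min_len = min_K + 1L)
  burst_pmf(pr, "count", eps = eps, params = spec)
}
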