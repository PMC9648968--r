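#' Likelihood-ratio confidence interval from a profile curve
#'
#' Low-level engine: given a function returning the profile negative
#' log-likelihood at fixed values of one parameter, locates the values where
#' the profile exceeds the minimum by `qchisq(level, 1) / 2` (1.9207 at 95%).
#' The scan is log-uniform over `[lower, upper]` and each threshold crossing
#' is refined by bisection.
#'
#' @param profile_fn Function of one scalar returning the profile NLL.
#' @param mle Parameter value at the full minimum.
#' @param nll_min NLL at the full minimum.
#' @param lower,upper Scan range (positive; log-spaced grid).
#' @param level Confidence level (default 0.95).
#' @param n_grid Grid points per side (default 20).
#' @param refine Bisection refinement steps per endpoint (default 20).
#' @return A list with `lower`, `upper`, `level`, `threshold`, and logical
#'   flags `lower_at_bound`, `upper_at_bound` set when the interval is
#'   one-sided because the scan hit the range boundary.
#' @export
profile_interval <- function(profile_fn, mle, nll_min, lower, upper,
                             level = 0.95, n_grid = 20L, refine = 20L) {
  if (lower <= 0) lower <- min(mle * 1e-3, 1e-6)
  thr <- nll_min + stats::qchisq(level, df = 1) / 2

  bisect <- function(in_val, out_val) {
    for (i in seq_len(refine)) {
      mid <- sqrt(in_val * out_val)  # geometric: scan is log-scaled
      if (profile_fn(mid) <= thr) in_val <- mid else out_val <- mid
    }
    sqrt(in_val * out_val)
  }

  scan_side <- function(from, to) {
    # walk from the MLE toward the bound until the profile exceeds thr
    grid <- exp(seq(log(from), log(to), length.out = n_grid))
    prev <- from
    for (g in grid[-1]) {
      if (profile_fn(g) > thr) return(list(val = bisect(prev, g), at_bound = FALSE))
      prev <- g
    }
    list(val = to, at_bound = TRUE)
  }

  lo <- scan_side(mle, lower)
  hi <- scan_side(mle, upper)
  list(lower = lo$val, upper = hi$val, level = level, threshold = thr,
       lower_at_bound = lo$at_bound, upper_at_bound = hi$at_bound)
}

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Scans fixed values of one transcriptional parameter, re-optimizing the
#' other two at each value (profile likelihood), and returns the level-set
#' interval of the likelihood-ratio statistic. The re-optimization is a
#' bounded quasi-Newton refinement started from the global fit, which is
#' adequate because the profile is scanned locally around the optimum.
#'
#' @param data The [observed_dataset] that was fitted.
#' @param fit The `fit_result` from [fit_kinetics()].
#' @param param One of `"sigma_on"`, `"sigma_off"`, `"rho"`.
#' @param level Confidence level (default 0.95).
#' @param n_grid Scan points per side (default 15).
#' @return As [profile_interval()], with the point estimate in `estimate`.
#' @export
profile_likelihood_ci <- function(data, fit, param = c("sigma_on", "sigma_off", "rho"),
                                  level = 0.95, n_grid = 15L) {
  stopifnot(inherits(data, "observed_dataset"), inherits(fit, "fit_result"))
  param <- match.arg(param)
  scale <- fit$scale
  space <- fit$space
  nm <- c("sigma_on", "sigma_off", "rho")
  i_fix <- match(param, nm)
  i_free <- setdiff(seq_len(3), i_fix)
  theta0 <- unlist(fit$theta_star[nm])

  nll_at <- function(theta) {
    p <- tryCatch(rate_params(theta[1], theta[2], theta[3]),
                  error = function(e) NULL)
    if (is.null(p)) return(1e300)
    v <- tryCatch(negative_log_likelihood(data, p, scale, warn = FALSE),
                  error = function(e) 1e300)
    if (is.finite(v)) v else 1e300
  }

  start_free <- pmax(theta0[i_free], 1e-6)
  profile_fn <- function(value) {
    objf <- function(free) {
      th <- numeric(3)
      th[i_fix] <- value
      th[i_free] <- free
      nll_at(th)
    }
    opt <- tryCatch(
      stats::optim(start_free, objf, method = "L-BFGS-B",
                   lower = pmax(space$lower[i_free], 1e-8),
                   upper = space$upper[i_free],
                   control = list(maxit = 60)),
      error = function(e) list(value = objf(start_free)))
    opt$value
  }

  res <- profile_interval(profile_fn, mle = theta0[i_fix], nll_min = fit$nll,
                          lower = max(space$lower[i_fix], theta0[i_fix] / 10),
                          upper = min(space$upper[i_fix], theta0[i_fix] * 10),
                          level = level, n_grid = n_grid)
  res$estimate <- theta0[i_fix]
  res$param <- param
  res
}
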