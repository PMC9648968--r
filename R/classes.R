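#' Kinetic parameters of the two-state promoter
#'
#' The telegraph (two-state) model describes a promoter switching between an
#' inactive (OFF) and an active (ON) state at rates `sigma_on` (OFF -> ON)
#' and `sigma_off` (ON -> OFF); transcription initiation occurs at rate `rho`
#' only while the promoter is ON. All rates are in 1/min.
#'
#' @param sigma_on Promoter activation rate (1/min).
#' @param sigma_off Promoter deactivation rate (1/min).
#' @param rho Transcription initiation rate in the ON state (1/min).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(sigma_on = 7.5, sigma_off = 7.5, rho = 50)
#' @export
rate_params <- function(sigma_on, sigma_off, rho) {
  vals <- c(sigma_on = sigma_on, sigma_off = sigma_off, rho = rho)
  if (!all(is.finite(vals))) {
    stop("rate parameters must be finite, got (",
         paste(signif(vals, 4), collapse = ", "), ")", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("rate parameters must be non-negative", call. = FALSE)
  }
  structure(list(sigma_on = sigma_on, sigma_off = sigma_off, rho = rho),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("<rate_params> sigma_on = %g, sigma_off = %g, rho = %g (1/min)\n",
              x$sigma_on, x$sigma_off, x$rho))
  invisible(x)
}

#' Gene geometry for the trapezoidal signal profile
#'
#' The fluorescent probes bind within the first `L1` base pairs of the
#' transcript (here, stem loops at the 5' end), so the signal of a single
#' elongating polymerase rises linearly over the probe region and plateaus
#' at 1 (in units of one complete mRNA) over the remaining `L2` base pairs
#' of the gene body.
#'
#' @param L1 Length of the 5' probe-binding region (bp), must be positive.
#' @param L2 Length of the downstream gene body (bp), non-negative.
#' @return An object of class `gene_geometry` with fields `L1`, `L2` and the
#'   total length `L = L1 + L2`.
#' @examples
#' gene_geometry(862, 2200)$L  # 3062
#' @export
gene_geometry <- function(L1 = 862, L2 = 2200) {
  if (!is.finite(L1) || L1 <= 0) stop("L1 must be positive", call. = FALSE)
  if (!is.finite(L2) || L2 < 0) stop("L2 must be non-negative", call. = FALSE)
  structure(list(L1 = L1, L2 = L2, L = L1 + L2), class = "gene_geometry")
}

#' @export
print.gene_geometry <- function(x, ...) {
  cat(sprintf("<gene_geometry> L1 = %g bp, L2 = %g bp, L = %g bp\n",
              x$L1, x$L2, x$L))
  invisible(x)
}

#' Telegraph model for mature mRNA
#'
#' Combines promoter kinetics with first-order mRNA degradation at rate `d`.
#' The steady-state mature mRNA distribution depends only on the ratios
#' `sigma_on/d`, `sigma_off/d`, `rho/d`, so `d` is fixed (not inferred) and
#' all fitted rates are interpreted relative to it.
#'
#' @param rates A [rate_params] object.
#' @param d mRNA degradation rate (1/min), must be positive. Default 1.
#' @return An object of class `mature_model`.
#' @export
mature_model <- function(rates, d = 1) {
  stopifnot(inherits(rates, "rate_params"))
  if (!is.finite(d) || d <= 0) stop("degradation rate d must be positive", call. = FALSE)
  structure(list(rates = rates, d = d), class = "mature_model")
}

#' Delay telegraph model for nascent (gene-bound) mRNA
#'
#' Each initiation event places one RNA polymerase II on the gene; the
#' polymerase travels at constant speed and leaves after a fixed residence
#' (elongation) time `tau`. The number of bound polymerases therefore follows
#' a delay telegraph model, and the transcription-site fluorescence follows
#' the trapezoidal profile defined by `geometry`.
#'
#' @param rates A [rate_params] object.
#' @param tau Elongation (residence) time in minutes, positive. Default 0.5.
#' @param geometry A [gene_geometry] object.
#' @return An object of class `nascent_model`.
#' @export
nascent_model <- function(rates, tau = 0.5, geometry = gene_geometry()) {
  stopifnot(inherits(rates, "rate_params"), inherits(geometry, "gene_geometry"))
  if (!is.finite(tau) || tau <= 0) stop("elongation time tau must be positive", call. = FALSE)
  structure(list(rates = rates, tau = tau, geometry = geometry),
            class = "nascent_model")
}

#' Elongation time from gene length and polymerase speed
#'
#' @param length_bp Transcript length in base pairs.
#' @param speed_bp_per_s Elongation speed in bp/s.
#' @param unit `"min"` (default) or `"s"`.
#' @return Elongation time in the requested unit.
#' @examples
#' elongation_time(3062, 65)        # ~0.785 min
#' elongation_time(3062, 65, "s")   # ~47.1 s
#' @export
elongation_time <- function(length_bp, speed_bp_per_s, unit = c("min", "s")) {
  unit <- match.arg(unit)
  if (length_bp <= 0 || speed_bp_per_s <= 0) {
    stop("length and speed must be positive", call. = FALSE)
  }
  secs <- length_bp / speed_bp_per_s
  if (unit == "s") secs else secs / 60
}

#' Derived bursting quantities
#'
#' Computes the fraction of time the promoter spends ON,
#' `fON = sigma_on / (sigma_on + sigma_off)`, the mean burst size
#' `rho / sigma_off` (transcripts initiated per ON period), and the effective
#' (time-averaged) transcription rate `rho * fON`.
#'
#' @param params A [rate_params] object.
#' @return A list with `fraction_on`, `burst_size`, `effective_rate`, and a
#'   logical `burst_size_infinite` flag set when `sigma_off == 0`.
#' @examples
#' derived_quantities(rate_params(1, 1, 100))  # fON = 0.5, effective 50
#' @export
derived_quantities <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  s_on <- params$sigma_on; s_off <- params$sigma_off; rho <- params$rho
  if (s_on + s_off == 0) {
    stop("fraction ON undefined: sigma_on + sigma_off = 0", call. = FALSE)
  }
  f_on <- s_on / (s_on + s_off)
  inf_burst <- s_off == 0
  list(
    fraction_on = f_on,
    burst_size = if (inf_burst) Inf else rho / s_off,
    effective_rate = rho * f_on,
    burst_size_infinite = inf_burst
  )
}

#' Fraction of ON time
#' @param params A [rate_params] object.
#' @return `sigma_on / (sigma_on + sigma_off)`.
#' @export
fraction_on <- function(params) derived_quantities(params)$fraction_on
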