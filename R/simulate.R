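# float-robust ceiling bin: signal in (i-1, i] -> i, zero -> 0; a relative
# tolerance keeps exact-integer signals (all polymerases on the plateau)
# from being pushed up a bin by round-off after gain rescaling
ceiling_bin <- function(x) as.integer(ceiling(x - 1e-9))

#' Simulation configuration
#'
#' @param n_cells Number of cells (independent stationary samples).
#' @param seed Integer seed; all simulators are deterministic given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells, seed = 1L) {
  if (!is.finite(n_cells) || n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate stationary mature mRNA counts (telegraph model)
#'
#' Stochastic simulation of the telegraph model, one steady-state mature
#' mRNA count per cell. The promoter is started from its stationary ON
#' probability and initiations over a window of 40 mean mRNA lifetimes are
#' thinned by their exponential survival, which samples the stationary count
#' distribution without a burn-in bias.
#'
#' @param spec A [mature_model].
#' @param cfg A [sim_config].
#' @param rho_per_cell Optional vector of per-cell initiation rates (length
#'   `n_cells`), e.g. from [perturb_initiation_rates()]; overrides
#'   `spec$rates$rho`.
#' @return Integer vector of counts, one per cell.
#' @examples
#' x <- simulate_mature_cells(mature_model(rate_params(1, 1, 10)), sim_config(1000, 7))
#' mean(x)
#' @export
simulate_mature_cells <- function(spec, cfg, rho_per_cell = NULL) {
  stopifnot(inherits(spec, "mature_model"), inherits(cfg, "sim_config"))
  rho <- .per_cell_rho(spec$rates$rho, rho_per_cell, cfg$n_cells)
  set.seed(cfg$seed)
  cpp_sim_mature(cfg$n_cells, spec$rates$sigma_on, spec$rates$sigma_off,
                 rho, spec$d, horizon = 40 / spec$d)
}

.per_cell_rho <- function(rho, rho_per_cell, n_cells) {
  if (is.null(rho_per_cell)) return(rho)
  if (length(rho_per_cell) != n_cells) {
    stop("rho_per_cell must have one entry per cell", call. = FALSE)
  }
  if (any(rho_per_cell < 0)) stop("per-cell rates must be non-negative", call. = FALSE)
  as.numeric(rho_per_cell)
}

#' Simulate stationary nascent transcription-site measurements
#'
#' Delayed stochastic simulation with fixed residence time `tau`: every
#' polymerase initiated within the last `tau` minutes is still on the gene.
#' Positions are elapsed-time fractions on the unit interval; the per-polymerase signal
#' follows the trapezoidal profile (`q(x) = x L / L1` up to `x = L1/L`, then
#' 1), the cell's continuous signal is the sum, and the integer bin is its
#' ceiling (signal in (i-1, i] maps to bin i, zero signal to bin 0) -- the
#' same right-closed convention used by [signal_bin_pmf()].
#'
#' @param spec A [nascent_model].
#' @param cfg A [sim_config].
#' @param rho_per_cell Optional per-cell initiation rates.
#' @return A data.frame with columns `cell`, `count` (bound Pol II number),
#'   `signal` (continuous), `bin` (integer), plus the per-polymerase
#'   positions as attribute `positions` (data.frame `cell`, `position`).
#' @export
simulate_nascent_cells <- function(spec, cfg, rho_per_cell = NULL) {
  stopifnot(inherits(spec, "nascent_model"), inherits(cfg, "sim_config"))
  rho <- .per_cell_rho(spec$rates$rho, rho_per_cell, cfg$n_cells)
  set.seed(cfg$seed)
  sim <- cpp_sim_nascent(cfg$n_cells, spec$rates$sigma_on, spec$rates$sigma_off,
                         rho, spec$tau, spec$geometry$L1 / spec$geometry$L)
  out <- data.frame(cell = seq_len(cfg$n_cells), count = sim$count,
                    signal = sim$signal, bin = ceiling_bin(sim$signal))
  attr(out, "positions") <- data.frame(cell = sim$cell, position = sim$position)
  out
}

#' Log-normal cell-to-cell perturbation of the initiation rate
#'
#' Models extrinsic (post-transcriptional) noise: each cell keeps one
#' initiation rate `rho'` for its whole history, drawn from a log-normal
#' distribution with arithmetic mean `rho` and standard deviation `cv * rho`
#' (log-scale parameters solved from these two moments).
#'
#' @param rho Mean initiation rate (1/min).
#' @param cv Coefficient of variation of the perturbation (e.g. 0.05 for 5%
#'   external noise); `cv = 0` returns the constant rate.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return Numeric vector of per-cell rates.
#' @export
perturb_initiation_rates <- function(rho, cv, n_cells, seed = 1L) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (cv == 0) return(rep(rho, n_cells))
  sdlog2 <- log(1 + cv^2)
  meanlog <- log(rho) - sdlog2 / 2
  set.seed(seed)
  stats::rlnorm(n_cells, meanlog = meanlog, sdlog = sqrt(sdlog2))
}

#' Simulate cells carrying two gene copies
#'
#' `independent` mode sums two independent single-copy simulations (the
#' post-replication G2 model used for fitting); `synchronized` mode drives
#' initiation at rate `2 rho` from one shared promoter trajectory (perfect
#' state correlation of the alleles).
#'
#' @param spec A [mature_model] or [nascent_model].
#' @param cfg A [sim_config].
#' @param mode `"independent"` or `"synchronized"`.
#' @return For mature models, an integer vector of total counts; for nascent
#'   models, a data.frame as in [simulate_nascent_cells()] with the summed
#'   signal rebinned.
#' @export
simulate_two_copy_cells <- function(spec, cfg, mode = c("independent", "synchronized")) {
  mode <- match.arg(mode)
  if (inherits(spec, "mature_model")) {
    if (mode == "synchronized") {
      spec2 <- mature_model(rate_params(spec$rates$sigma_on, spec$rates$sigma_off,
                                        2 * spec$rates$rho), d = spec$d)
      return(simulate_mature_cells(spec2, cfg))
    }
    a <- simulate_mature_cells(spec, cfg)
    b <- simulate_mature_cells(spec, sim_config(cfg$n_cells, cfg$seed + 1000003L))
    return(a + b)
  }
  if (inherits(spec, "nascent_model")) {
    if (mode == "synchronized") {
      spec2 <- nascent_model(rate_params(spec$rates$sigma_on, spec$rates$sigma_off,
                                         2 * spec$rates$rho),
                             tau = spec$tau, geometry = spec$geometry)
      return(simulate_nascent_cells(spec2, cfg))
    }
    a <- simulate_nascent_cells(spec, cfg)
    b <- simulate_nascent_cells(spec, sim_config(cfg$n_cells, cfg$seed + 1000003L))
    sig <- a$signal + b$signal
    out <- data.frame(cell = a$cell, count = a$count + b$count,
                      signal = sig, bin = ceiling_bin(sig))
    return(out)
  }
  stop("spec must be a mature_model or nascent_model", call. = FALSE)
}

#' Simulate a live-cell-like transcription-site intensity trace
#'
#' One stationary trajectory of the delay telegraph model, with the total
#' trapezoidal signal evaluated on a regular time grid (no discretization).
#'
#' @param spec A [nascent_model].
#' @param duration Trace length (min).
#' @param dt Sampling interval (min), `0 < dt < duration`.
#' @param seed Integer seed.
#' @return Numeric vector of signal values at times `seq(0, duration, by = dt)`.
#' @export
simulate_intensity_trace <- function(spec, duration = 120, dt = 0.1, seed = 1L) {
  stopifnot(inherits(spec, "nascent_model"))
  if (!(duration > dt && dt > 0)) stop("need duration > dt > 0", call. = FALSE)
  set.seed(seed)
  cpp_sim_trace(spec$rates$sigma_on, spec$rates$sigma_off, spec$rates$rho,
                spec$tau, spec$geometry$L1 / spec$geometry$L, duration, dt)
}

#' Simulate integrated DNA-stain intensities for a G1/G2 mixture
#'
#' Fixture generator for the cell-cycle classifier: a two-component Gaussian
#' mixture of integrated nuclear DNA-stain (e.g. DAPI) intensities with
#' ground-truth phase labels.
#'
#' @param n_g1,n_g2 Cells in each phase.
#' @param means Length-2 vector of component means (G2 mean > G1 mean).
#' @param sds Length-2 vector of positive component standard deviations.
#' @param seed Integer seed.
#' @return A data.frame with columns `intensity` and `true_phase`.
#' @export
simulate_dna_content <- function(n_g1, n_g2, means = c(100, 200),
                                 sds = c(10, 20), seed = 1L) {
  if (any(means <= 0) || any(sds <= 0)) stop("means and sds must be positive", call. = FALSE)
  if (n_g2 > 0 && n_g1 > 0 && means[2] <= means[1]) {
    stop("G2 mean must exceed G1 mean", call. = FALSE)
  }
  set.seed(seed)
  x <- c(stats::rnorm(n_g1, means[1], sds[1]), stats::rnorm(n_g2, means[2], sds[2]))
  data.frame(intensity = x,
             true_phase = rep(c("G1", "G2"), c(n_g1, n_g2)))
}

#' Corrupt low signal bins to emulate transcription-site misidentification
#'
#' When the transcription site is defined as the brightest nuclear spot, a
#' silent cell's brightest mature mRNA can be misread as a weak nascent
#' signal, inflating the low bins at the expense of bin 0. This helper
#' redistributes a fraction of the zero-bin cells uniformly over the bins in
#' `into`, producing the artifact that the fusion and rejection curation
#' methods are designed to absorb.
#'
#' @param bins Integer vector of per-cell signal bins.
#' @param fraction Fraction of bin-0 cells to displace (default 0.2).
#' @param into Bins receiving the displaced cells (default 1:3).
#' @param seed Integer seed.
#' @return Integer vector of corrupted bins.
#' @export
corrupt_low_bins <- function(bins, fraction = 0.2, into = 1:3, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  zero <- which(bins == 0L)
  n_move <- floor(fraction * length(zero))
  if (n_move == 0L) return(as.integer(bins))
  moved <- sample(zero, n_move)
  bins[moved] <- sample(as.integer(into), n_move, replace = TRUE)
  as.integer(bins)
}
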