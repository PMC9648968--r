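# shared fixtures: geometry of the probed gene and parameter sets spanning
# low / balanced / high fraction-ON regimes
gg <- gene_geometry(862, 2200)

params_fon <- list(
  low  = rate_params(sigma_on = 1.5, sigma_off = 6, rho = 40),   # fON = 0.2
  mid  = rate_params(sigma_on = 4,   sigma_off = 4, rho = 40),   # fON = 0.5
  high = rate_params(sigma_on = 6,   sigma_off = 1.5, rho = 40)  # fON = 0.8
)

empirical_pmf <- function(values, K) {
  tabulate(values + 1L, nbins = K + 1L) / length(values)
}

quick_ctl <- function(seed = 1L, ...) {
  fit_control(pop = 25, max_gen = 60, patience = 25, restarts = 1,
              seed = seed, ...)
}
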