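test_that("telegraph steady state reproduces analytic limits", {
  # always-ON gene: Poisson(rho / d)
  p <- telegraph_pmf(mature_model(rate_params(1, 0, 5), d = 1))
  expect_equal(p$probs[1], exp(-5), tolerance = 1e-8)
  expect_lt(total_variation(p$probs, dpois(0:p$K, 5)), 1e-8)

  # silent gene: all mass at zero
  expect_equal(telegraph_pmf(mature_model(rate_params(1, 1, 0)))$probs[1], 1)
  expect_equal(telegraph_pmf(mature_model(rate_params(0, 1, 10)))$probs[1], 1)

  # normalization within the configured tail bound, across regimes
  for (pr in params_fon) {
    pmf <- telegraph_pmf(mature_model(pr, d = 1))
    expect_gte(sum(pmf$probs), 1 - 1e-8)
    expect_lte(sum(pmf$probs), 1 + 1e-12)
  }
})

test_that("telegraph_pmf rejects invalid input and reports truncation failure", {
  expect_error(rate_params(NaN, 1, 5), "finite")
  expect_error(rate_params(-1, 1, 5), "non-negative")
  expect_error(telegraph_pmf(mature_model(rate_params(1, 1, 10)), eps = 0), "eps")
  expect_error(telegraph_pmf(mature_model(rate_params(1, 1, 100)), max_K = 20),
               "max_K")
})

test_that("telegraph pmf matches a 1e5-sample SSA oracle", {
  spec <- mature_model(rate_params(1, 1, 10), d = 1)
  pmf <- telegraph_pmf(spec)
  x <- simulate_mature_cells(spec, sim_config(1e5, 421))
  expect_lt(total_variation(empirical_pmf(x, max(pmf$K, max(x))), pmf$probs), 0.02)
})

test_that("delay telegraph solver is exact in the always-ON limit and on the mean", {
  q <- delay_polii_pmf(nascent_model(rate_params(1, 0, 4), tau = 0.5))
  expect_equal(q$probs[1], exp(-2), tolerance = 1e-8)
  expect_lt(total_variation(q$probs, dpois(0:q$K, 2)), 1e-8)

  # E[k] = rho * tau * fON across regimes, relative error < 1e-6
  for (pr in params_fon) {
    for (tau in c(0.25, 0.5)) {
      pk <- delay_polii_pmf(nascent_model(pr, tau = tau))
      want <- pr$rho * tau * pr$sigma_on / (pr$sigma_on + pr$sigma_off)
      expect_lt(abs(pmf_mean(pk) - want) / want, 1e-6)
    }
  }
  expect_equal(pmf_mean(delay_polii_pmf(nascent_model(rate_params(1, 1, 4), tau = 0.5))),
               1, tolerance = 1e-6)
})

test_that("delay telegraph pmf matches a 1e5-cell delayed-SSA oracle", {
  spec <- nascent_model(rate_params(2, 3, 20), tau = 0.5, geometry = gg)
  pk <- delay_polii_pmf(spec)
  ns <- simulate_nascent_cells(spec, sim_config(1e5, 422))
  expect_lt(total_variation(empirical_pmf(ns$count, max(pk$K, max(ns$count))),
                            pk$probs), 0.02)
})

test_that("conditional signal bins follow the binomial/uniform-sum mixture", {
  expect_equal(signal_conditional_bin_probs(0, gg), 1)
  expect_equal(signal_conditional_bin_probs(1, gg), c(0, 1))
  b2 <- signal_conditional_bin_probs(2, gg)
  a <- gg$L1 / gg$L
  expect_equal(b2[2], a^2 / 2, tolerance = 1e-12)
  expect_equal(b2[3], 1 - a^2 / 2, tolerance = 1e-12)
  expect_error(signal_conditional_bin_probs(-1, gg), "non-negative")

  # Monte-Carlo oracle: each polymerase contributes Uniform(0,1) w.p. L1/L,
  # else exactly 1; bins are the ceiling of the sum
  set.seed(99)
  n_mc <- 1e6
  for (k in 2:5) {
    u <- matrix(runif(n_mc * k), ncol = k)
    is_unif <- matrix(runif(n_mc * k) < a, ncol = k)
    s <- rowSums(ifelse(is_unif, u, 1))
    emp <- tabulate(ceiling(s), nbins = k) / n_mc   # bins 1..k (k >= 1 here)
    model <- signal_conditional_bin_probs(k, gg)[-1]
    se <- sqrt(pmax(model * (1 - model), 1e-12) / n_mc)
    expect_true(all(abs(emp - model) <= 3 * se + 1e-9),
                label = sprintf("k = %d bins within 3 Monte-Carlo SE", k))
  }
})

test_that("binned signal distribution has the analytic mean and normalization", {
  # silent gene: all mass in bin 0
  s0 <- signal_bin_pmf(nascent_model(rate_params(1, 1, 0), geometry = gg))
  expect_equal(s0$probs[1], 1)

  # always-ON: continuous mean = rho * tau * (L1/2 + L2) / L
  spec <- nascent_model(rate_params(1, 0, 4), tau = 0.5, geometry = gg)
  pk <- delay_polii_pmf(spec)
  per_pol <- (gg$L1 / 2 + gg$L2) / gg$L
  expect_equal(pmf_mean(pk) * per_pol, 2 * (431 + 2200) / 3062, tolerance = 1e-4)

  s <- signal_bin_pmf(spec)
  expect_gte(sum(s$probs), 1 - 1e-8)

  # binned mean bracketed by the continuous mean and its +1 shift
  cont <- pmf_mean(pk) * per_pol
  expect_gte(pmf_mean(s), cont - 1e-6)
  expect_lte(pmf_mean(s), cont + 1)
})

test_that("binned signal matches delayed-SSA discretization where positions are iid", {
  # always-ON and fast-switching regimes: the uniform-position mixture is
  # exact (Poisson order statistics) or near-exact, so the match is at
  # sampling level
  for (pr in list(rate_params(1, 0, 20), rate_params(20, 30, 20))) {
    spec <- nascent_model(pr, tau = 0.5, geometry = gg)
    sp <- signal_bin_pmf(spec)
    ns <- simulate_nascent_cells(spec, sim_config(1e5, 423))
    expect_lt(total_variation(empirical_pmf(ns$bin, max(sp$K, max(ns$bin))),
                              sp$probs), 0.02)
  }
  # slow switching: positions given the count are no longer independent of
  # the promoter history; the residual model-vs-simulation bias stays small
  spec <- nascent_model(rate_params(2, 3, 20), tau = 0.5, geometry = gg)
  sp <- signal_bin_pmf(spec)
  ns <- simulate_nascent_cells(spec, sim_config(1e5, 424))
  expect_lt(total_variation(empirical_pmf(ns$bin, max(sp$K, max(ns$bin))),
                            sp$probs), 0.05)
})

test_that("convolution adds means and conserves mass", {
  d0 <- burst_pmf(1)
  expect_equal(convolve_pmf(d0, d0)$probs, 1)
  u <- burst_pmf(c(0.5, 0.5))
  expect_equal(convolve_pmf(u, u)$probs, c(0.25, 0.5, 0.25))

  lam <- 3.5
  pois <- burst_pmf(dpois(0:60, lam))
  conv <- convolve_pmf(pois, pois)
  expect_lt(total_variation(conv$probs, dpois(0:conv$K, 2 * lam)), 1e-10)
  expect_equal(pmf_mean(conv), 2 * pmf_mean(pois), tolerance = 1e-10)
  expect_equal(sum(conv$probs), sum(pois$probs)^2, tolerance = 1e-12)

  expect_error(convolve_pmf(burst_pmf(1, "count"), burst_pmf(1, "signal")),
               "bin conventions")
})

test_that("derived quantities follow the closed forms", {
  d <- derived_quantities(rate_params(1, 1, 100))
  expect_equal(d$fraction_on, 0.5)
  expect_equal(d$effective_rate, 50)
  expect_equal(derived_quantities(rate_params(1, 10, 50))$burst_size, 5)
  d2 <- derived_quantities(rate_params(3, 1, 40))
  expect_equal(d2$fraction_on, 0.75)
  expect_equal(d2$effective_rate, 30)

  expect_error(derived_quantities(rate_params(0, 0, 10)), "undefined")
  d3 <- derived_quantities(rate_params(1, 0, 10))
  expect_true(d3$burst_size_infinite)
  expect_identical(d3$burst_size, Inf)
})

test_that("Fano factor is 1 for Poisson, 0 for degenerate, and matches SSA", {
  pois <- burst_pmf(dpois(0:80, 7))
  expect_equal(fano_factor(pois), 1, tolerance = 1e-8)
  delta5 <- burst_pmf(c(0, 0, 0, 0, 0, 1))
  expect_equal(fano_factor(delta5), 0)
  expect_error(fano_factor(burst_pmf(c(1))), "zero mean")

  spec <- mature_model(rate_params(1, 1, 10), d = 1)
  x <- simulate_mature_cells(spec, sim_config(1e6, 77))
  expect_equal(fano_factor(telegraph_pmf(spec)), var(x) / mean(x),
               tolerance = 0.02)
})

test_that("PMFs round-trip through CSV and serialize to JSON", {
  p <- telegraph_pmf(mature_model(rate_params(2, 3, 15)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pmf_csv(p, path)
  q <- read_pmf_csv(path, kind = "count")
  expect_equal(q$probs, p$probs, tolerance = 1e-12)

  js <- jsonlite::fromJSON(pmf_to_json(p))
  expect_equal(js$K, p$K)
  expect_equal(js$probs, p$probs, tolerance = 1e-12)
  expect_equal(js$params$rates$rho, 15)
})

test_that("elongation-time helper converts length and speed", {
  expect_equal(elongation_time(3062, 65, "s"), 3062 / 65)
  expect_equal(elongation_time(3062, 65), 3062 / 65 / 60)
  expect_error(elongation_time(0, 65), "positive")
})
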