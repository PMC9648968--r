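test_that("negative log-likelihood reduces to hand-computable cases", {
  # model with P(0) = P(1) = 1/2 at sigma_on = sigma_off, rho chosen so that
  # the likelihood of {0, 1} is 2 log 2: verified against a direct lookup
  d <- observed_dataset(c(0L, 1L), kind = "mature-counts")
  pr <- rate_params(2, 3, 15)
  pmf <- telegraph_pmf(mature_model(pr, d = 1), min_K = 1)
  want <- -(log(pmf$probs[1]) + log(pmf$probs[2]))
  expect_equal(negative_log_likelihood(d, pr), want, tolerance = 1e-9)

  # certain outcome gives zero NLL: silent gene, all-zero data
  d0 <- observed_dataset(rep(0L, 5), kind = "mature-counts")
  expect_equal(negative_log_likelihood(d0, rate_params(1, 1, 0)), 0)

  expect_error(observed_dataset(integer(0)), "empty")
  expect_error(observed_dataset(c(-1L, 2L)), "non-negative")
})

test_that("NLL is permutation invariant and histogram-consistent", {
  set.seed(10)
  vals <- simulate_mature_cells(mature_model(rate_params(2, 3, 20)),
                                sim_config(2000, 13))
  pr <- rate_params(2, 3, 20)
  a <- negative_log_likelihood(observed_dataset(vals, "mature-counts"), pr)
  b <- negative_log_likelihood(observed_dataset(sample(vals), "mature-counts"), pr)
  expect_equal(a, b, tolerance = 1e-12)

  # per-cell sum equals the multiplicity-weighted histogram evaluation
  pmf <- telegraph_pmf(mature_model(pr), min_K = max(vals))
  per_cell <- -sum(log(pmax(pmf$probs[vals + 1L], 1e-15)))
  expect_equal(a, per_cell, tolerance = 1e-9)
})

test_that("two-copy and curation variants transform the likelihood correctly", {
  pr <- rate_params(2, 3, 10)
  vals <- c(0L, 2L, 5L, 9L)
  # independent copies: model is the self-convolution
  d2 <- observed_dataset(vals, "mature-counts", copy_mode = "two-copy-independent")
  p1 <- telegraph_pmf(mature_model(pr), min_K = max(vals))
  p2 <- convolve_pmf(p1, p1)
  want <- -sum(log(p2$probs[vals + 1L]))
  expect_equal(negative_log_likelihood(d2, pr), want, tolerance = 1e-6)

  # synchronized copies: single trajectory at doubled rho
  ds <- observed_dataset(vals, "mature-counts", copy_mode = "two-copy-synchronized")
  pd <- telegraph_pmf(mature_model(rate_params(2, 3, 20)), min_K = max(vals))
  expect_equal(negative_log_likelihood(ds, pr),
               -sum(log(pd$probs[vals + 1L])), tolerance = 1e-6)
})

test_that("fusion curation merges low bins and conserves probability", {
  p <- burst_pmf(c(0.1, 0.1, 0.1, 0.1, 0.6), "signal")
  # k = 1 is the identity
  f1 <- curate_fusion(p, c(0L, 4L), k = 1)
  expect_identical(f1$pmf$probs, p$probs)
  expect_identical(f1$values, c(0L, 4L))

  f4 <- curate_fusion(p, c(0L, 1L, 2L, 3L, 4L), k = 4)
  expect_equal(f4$pmf$probs, c(0.4, 0.6))
  expect_equal(f4$values, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(sum(f4$pmf$probs), sum(p$probs), tolerance = 1e-12)
  expect_error(curate_fusion(p, 0L, k = 9), "support")
})

test_that("rejection curation conditions the model on surviving bins", {
  p <- burst_pmf(c(0.25, 0.25, 0.5), "signal")
  r1 <- curate_rejection(p, c(0L, 1L, 2L), k = 1)
  expect_equal(sum(r1$pmf$probs), 1, tolerance = 1e-12)
  expect_equal(r1$values, c(0L, 1L))

  r2 <- curate_rejection(p, c(0L, 1L, 2L, 2L), k = 2)
  expect_equal(r2$pmf$probs, 1)
  expect_equal(r2$values, c(0L, 0L))
  expect_error(curate_rejection(p, c(0L, 1L), k = 2), "every cell")
})

test_that("the likelihood concentrates at the true parameters", {
  truth <- rate_params(4, 4, 40)
  spec <- mature_model(truth)
  better <- 0L
  for (s in 1:10) {
    x <- simulate_mature_cells(spec, sim_config(1e4, 700 + s))
    d <- observed_dataset(x, "mature-counts")
    nll_true <- negative_log_likelihood(d, truth)
    nll_pert <- negative_log_likelihood(d, rate_params(8, 2, 80))
    if (nll_true < nll_pert) better <- better + 1L
  }
  expect_gte(better, 8L)
})

test_that("fitting recovers parameters and flags degenerate data", {
  truth <- rate_params(7.5, 7.5, 50)
  x <- simulate_mature_cells(mature_model(truth), sim_config(1e4, 808))
  f <- fit_kinetics(observed_dataset(x, "mature-counts"),
                    control = quick_ctl(seed = 9))
  expect_s3_class(f, "fit_result")
  expect_lt(abs(f$theta_star$rho - 50) / 50, 0.15)
  expect_lt(abs(f$derived$fraction_on - 0.5), 0.07)
  expect_true(is.finite(f$nll))
  expect_false(f$degenerate)

  fz <- fit_kinetics(observed_dataset(rep(0L, 200), "mature-counts"),
                     control = fit_control(pop = 10, max_gen = 10,
                                           patience = 5, restarts = 1))
  expect_true(fz$degenerate)
  expect_lt(fz$theta_star$rho * fz$derived$fraction_on, 1)
  expect_lt(fz$nll, 1)
})

test_that("curated likelihoods remain valid probability models during fitting", {
  truth <- rate_params(5, 5, 30)
  spec <- nascent_model(truth, tau = 0.5, geometry = gg)
  ns <- simulate_nascent_cells(spec, sim_config(4000, 815))
  # fusion k = 1 is exactly the uncurated likelihood
  d_plain <- observed_dataset(ns$bin, "nascent-bins")
  d_f1 <- observed_dataset(ns$bin, "nascent-bins", curation = "fusion",
                           curation_k = 1)
  expect_equal(negative_log_likelihood(d_plain, truth),
               negative_log_likelihood(d_f1, truth), tolerance = 1e-12)
  # rejection NLL is computed from a renormalized conditional model, so it
  # is bounded by n_surviving * log(1 / max p) and finite
  d_r2 <- observed_dataset(ns$bin, "nascent-bins", curation = "rejection",
                           curation_k = 2)
  expect_true(is.finite(negative_log_likelihood(d_r2, truth)))
})

test_that("profile intervals match the quadratic (Gaussian) benchmark", {
  # toy: NLL of a Gaussian mean with known sd -> profile CI must equal
  # mle +/- 1.96 se on a quadratic surface
  n <- 50; sigma <- 2; mle <- 10
  nll <- function(mu) n * (mu - mle)^2 / (2 * sigma^2)
  se <- sigma / sqrt(n)
  ci <- profile_interval(nll, mle = mle, nll_min = 0,
                         lower = mle / 10, upper = mle * 10,
                         n_grid = 40, refine = 40)
  expect_false(ci$lower_at_bound || ci$upper_at_bound)
  expect_equal(ci$upper - mle, 1.96 * se, tolerance = 0.05)
  expect_equal(mle - ci$lower, 1.96 * se, tolerance = 0.05)
})

test_that("profile likelihood CIs bracket the estimate and shrink with n", {
  truth <- rate_params(7.5, 7.5, 50)
  spec <- mature_model(truth)
  widths <- sapply(c(1000L, 8000L), function(n) {
    x <- simulate_mature_cells(spec, sim_config(n, 820))
    d <- observed_dataset(x, "mature-counts")
    f <- fit_kinetics(d, control = quick_ctl(seed = 21))
    ci <- profile_likelihood_ci(d, f, "rho", n_grid = 8)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
    ci$upper - ci$lower
  })
  expect_lt(widths[2], widths[1])
})
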