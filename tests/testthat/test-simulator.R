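test_that("simulators are deterministic given the seed", {
  spec_m <- mature_model(rate_params(2, 3, 20))
  expect_identical(simulate_mature_cells(spec_m, sim_config(500, 11)),
                   simulate_mature_cells(spec_m, sim_config(500, 11)))
  spec_n <- nascent_model(rate_params(2, 3, 20), geometry = gg)
  a <- simulate_nascent_cells(spec_n, sim_config(500, 11))
  b <- simulate_nascent_cells(spec_n, sim_config(500, 11))
  expect_identical(a$signal, b$signal)
  expect_identical(simulate_dna_content(100, 100, seed = 4),
                   simulate_dna_content(100, 100, seed = 4))
  expect_identical(simulate_intensity_trace(spec_n, 30, 0.1, seed = 9),
                   simulate_intensity_trace(spec_n, 30, 0.1, seed = 9))
  # different seed, different draw
  expect_false(identical(simulate_mature_cells(spec_m, sim_config(500, 11)),
                         simulate_mature_cells(spec_m, sim_config(500, 12))))
})

test_that("mature simulator hits Poisson and silent limits", {
  expect_true(all(simulate_mature_cells(mature_model(rate_params(1, 1, 0)),
                                        sim_config(2000, 1)) == 0))
  x <- simulate_mature_cells(mature_model(rate_params(1, 0, 5), d = 1),
                             sim_config(1e4, 2))
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / 1e4))
})

test_that("mature and nascent simulators match the model PMFs across fON regimes", {
  for (nm in names(params_fon)) {
    pr <- params_fon[[nm]]
    spec_m <- mature_model(pr, d = 1)
    pm <- telegraph_pmf(spec_m)
    x <- simulate_mature_cells(spec_m, sim_config(1e5, 500 + match(nm, names(params_fon))))
    expect_lt(total_variation(empirical_pmf(x, max(pm$K, max(x))), pm$probs), 0.02)

    spec_n <- nascent_model(pr, tau = 0.5, geometry = gg)
    pk <- delay_polii_pmf(spec_n)
    ns <- simulate_nascent_cells(spec_n, sim_config(1e5, 600 + match(nm, names(params_fon))))
    expect_lt(total_variation(empirical_pmf(ns$count, max(pk$K, max(ns$count))),
                              pk$probs), 0.02)
  }
})

test_that("nascent trapezoid mapping and discretization are consistent", {
  spec <- nascent_model(rate_params(2, 3, 20), geometry = gg)
  ns <- simulate_nascent_cells(spec, sim_config(5000, 31))
  expect_true(all(ns$signal[ns$count == 0] == 0))
  expect_true(all(ns$bin == ceiling(ns$signal)))          # round-trip exact
  expect_true(all(ns$signal <= ns$count + 1e-12))          # q(x) <= 1 per Pol II

  # plateau onset: a polymerase at x = L1/L contributes exactly 1
  a <- gg$L1 / gg$L
  q <- function(x) ifelse(x <= a, x / a, 1)
  expect_equal(q(a), 1)
  expect_equal(q(a / 2), 0.5)

  pos <- attr(ns, "positions")
  expect_true(all(pos$position >= 0 & pos$position <= 1))
  expect_equal(nrow(pos), sum(ns$count))
})

test_that("stationary Pol II positions are uniform along the gene", {
  # always-ON: pooled positions are exactly iid uniform (order statistics)
  spec <- nascent_model(rate_params(1, 0, 20), geometry = gg)
  ns <- simulate_nascent_cells(spec, sim_config(2e4, 41))
  pos <- attr(ns, "positions")$position
  ks <- suppressWarnings(ks.test(pos, "punif"))
  expect_gt(ks$p.value, 1e-3)

  # switching promoter: within-cell correlation precludes an iid KS test,
  # but the pooled marginal must still be uniform
  spec2 <- nascent_model(rate_params(2, 3, 20), geometry = gg)
  ns2 <- simulate_nascent_cells(spec2, sim_config(1e5, 42))
  pos2 <- attr(ns2, "positions")$position
  expect_gt(length(pos2), 1e5)
  dec <- tabulate(ceiling(pos2 * 10), nbins = 10) / length(pos2)
  expect_lt(max(abs(dec - 0.1)), 0.01)
})

test_that("log-normal rate perturbation matches the requested moments", {
  expect_identical(perturb_initiation_rates(100, 0, 5), rep(100, 5))
  expect_error(perturb_initiation_rates(100, -0.1, 5), "non-negative")

  r5 <- perturb_initiation_rates(100, 0.05, 1e5, seed = 7)
  expect_lt(abs(mean(r5) - 100), 3 * 5 / sqrt(1e5))
  expect_lt(abs(sd(r5) - 5) / 5, 0.05)

  r10 <- perturb_initiation_rates(100, 0.10, 1e5, seed = 8)
  expect_lt(abs(sd(r10) - 10) / 10, 0.05)
  expect_lt(abs(mean(r10) - 100), 3 * 10 / sqrt(1e5))
})

test_that("two-copy totals match the convolved single-copy model", {
  mm0 <- mature_model(rate_params(1, 1, 0))
  expect_true(all(simulate_two_copy_cells(mm0, sim_config(1000, 3)) == 0))

  mm <- mature_model(rate_params(1, 0, 5))
  tot <- simulate_two_copy_cells(mm, sim_config(1e5, 4))
  expect_lt(total_variation(empirical_pmf(tot, max(39, max(tot))),
                            dpois(0:max(39, max(tot)), 10)), 0.02)

  mm2 <- mature_model(rate_params(2, 3, 20))
  tot2 <- simulate_two_copy_cells(mm2, sim_config(1e5, 5))
  p1 <- telegraph_pmf(mm2)
  p2 <- convolve_pmf(p1, p1)
  expect_lt(total_variation(empirical_pmf(tot2, max(p2$K, max(tot2))), p2$probs),
            0.02)

  # synchronized copies = one trajectory at doubled initiation rate
  sync <- simulate_two_copy_cells(mm2, sim_config(1e5, 6), mode = "synchronized")
  psync <- telegraph_pmf(mature_model(rate_params(2, 3, 40)))
  expect_lt(total_variation(empirical_pmf(sync, max(psync$K, max(sync))),
                            psync$probs), 0.02)
  expect_error(simulate_two_copy_cells(mm2, sim_config(10, 1), mode = "both"),
               "arg")
})

test_that("intensity traces are stationary with the analytic time average", {
  spec0 <- nascent_model(rate_params(1, 1, 0), geometry = gg)
  expect_true(all(simulate_intensity_trace(spec0, 20, 0.1, seed = 2) == 0))

  spec <- nascent_model(rate_params(1, 0, 20), tau = 0.5, geometry = gg)
  tr <- simulate_intensity_trace(spec, duration = 400, dt = 0.1, seed = 3)
  want <- 20 * 0.5 * (gg$L1 / 2 + gg$L2) / gg$L
  # conservative SE for the time average of a correlated trace:
  # var(signal) ~ mean (Poisson-like), correlation time ~ tau
  se <- sqrt(want * 0.5 / 400)
  expect_lt(abs(mean(tr) - want), 3 * se)

  h <- length(tr) %/% 2
  m1 <- mean(tr[1:h]); m2 <- mean(tr[(h + 1):length(tr)])
  expect_lt(abs(m1 - m2), 4 * sqrt(2) * se)
})

test_that("DNA-content fixture has labeled, well-separated components", {
  expect_error(simulate_dna_content(10, 10, means = c(100, 100)), "exceed")
  uni <- simulate_dna_content(500, 0, seed = 5)
  expect_true(all(uni$true_phase == "G1"))
  mix <- simulate_dna_content(600, 400, means = c(100, 200), sds = c(10, 20),
                              seed = 6)
  expect_equal(nrow(mix), 1000)
  expect_equal(sum(mix$true_phase == "G2"), 400)
})
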