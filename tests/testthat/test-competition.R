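test_that("competition trajectory is the sum of two diluted exponentials", {
  cp <- competition_params(mu_wt = 0.1, mu_evo = 0.3, emergence_batch = 1,
                           initial_fraction = 0.2, n_batches = 3,
                           f_dil = 10, X0 = 5)
  tt <- c(6, 12)
  grid <- seq(0, 16, by = 0.5)
  tr <- competition_trajectory(cp, tt, grid)
  # oracle: run each subpopulation through the single-strain model
  wt <- rbale_trajectory(rbale_params(mu = rep(0.1, 3), f_dil = 10, X0 = 4),
                         tt, grid)
  mut <- rbale_trajectory(rbale_params(mu = rep(0.3, 3), f_dil = 10, X0 = 1),
                          tt, grid)
  expect_equal(tr$biomass_wt, wt$biomass, tolerance = 1e-10)
  expect_equal(tr$biomass_mut, mut$biomass, tolerance = 1e-10)
  expect_equal(tr$biomass, tr$biomass_wt + tr$biomass_mut)
})

test_that("apparent rates match a direct fold-change computation", {
  cp <- competition_params(mu_wt = 0.085, mu_evo = 0.21, emergence_batch = 2,
                           initial_fraction = 1e-4, n_batches = 6)
  tt <- seq(7, by = 7, length.out = 5)
  ar <- competition_apparent_rates(cp, tt, t_end = 42)
  eps <- 1e-9
  for (b in 1:6) {
    t0 <- c(0, tt)[b]
    t1 <- c(tt, 42)[b] - eps       # just before the dilution
    tr <- competition_trajectory(cp, tt, grid = c(t0, t1))
    direct <- log(tr$biomass[2] / tr$biomass[1]) / (t1 - t0)
    expect_equal(ar$apparent_mu[b], direct, tolerance = 1e-6)
  }
})

test_that("a vanishing mutant fraction leaves the wild-type rate", {
  cp <- competition_params(mu_wt = 0.085, mu_evo = 0.21, emergence_batch = 1,
                           initial_fraction = 1e-12, n_batches = 2)
  ar <- competition_apparent_rates(cp, transfer_times = 7, t_end = 14)
  expect_equal(ar$apparent_mu[1], 0.085, tolerance = 1e-6)
})

test_that("apparent rates rise monotonically from mu_wt to mu_evo", {
  cp <- competition_params(mu_wt = 0.085, mu_evo = 0.21, emergence_batch = 2,
                           initial_fraction = 1e-6, n_batches = 40)
  tt <- seq(10, by = 10, length.out = 39)
  ar <- competition_apparent_rates(cp, tt, t_end = 400)
  expect_true(all(diff(ar$apparent_mu) >= -1e-12))
  expect_true(all(ar$apparent_mu >= 0.085 - 1e-12))
  expect_true(all(ar$apparent_mu <= 0.21 + 1e-12))
  expect_equal(ar$apparent_mu[40], 0.21, tolerance = 1e-3)
})

test_that("competition parameter invariants are enforced", {
  expect_error(competition_params(0.2, 0.1), "mu_evo > mu_wt")
  expect_error(competition_params(0.1, 0.2, initial_fraction = 1.5), "0, 1")
  expect_error(competition_params(0.1, 0.2, emergence_batch = 20,
                                  n_batches = 16), "within the run")
})
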