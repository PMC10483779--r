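test_that("noiseless data are recovered exactly", {
  d <- gen_rbale_dataset("constant", n_batches = 6,
                         noise = noise_model(cv = 0), seed = 1)
  fit <- fit_rbale(d$ts, d$events, n_starts = 3)
  expect_true(fit$converged)
  expect_equal(fit$per_batch$mu_est, rep(0.41, 6), tolerance = 1e-6)
  expect_equal(fit$f_dil, 17, tolerance = 1e-6)
  expect_equal(fit$X0, 8, tolerance = 1e-5)
  expect_lt(fit$objective, 1e-12)
})

test_that("model-based rates agree with the log-linear oracle", {
  d <- gen_rbale_dataset("switching", n_batches = 8,
                         noise = noise_model(cv = 0), seed = 1)
  fit <- fit_rbale(d$ts, d$events, n_starts = 3)
  oracle <- loglinear_mu(segment_and_normalize(d$ts, d$events))
  expect_equal(fit$per_batch$mu_est, oracle$mu_hat, tolerance = 0.01)
})

test_that("noisy per-batch rates stay within five percent of truth", {
  d <- gen_rbale_dataset("constant", n_batches = 16,
                         noise = noise_model(cv = 0.02), seed = 2)
  fit <- fit_rbale(d$ts, d$events, n_starts = 5, seed = 2)
  expect_true(all(abs(fit$per_batch$mu_est / 0.41 - 1) < 0.05))
  expect_equal(mean(fit$per_batch$mu_est), 0.41, tolerance = 0.02)
  expect_equal(fit$f_dil, 17, tolerance = 0.05)
})

test_that("estimates of a switching run reproduce the monotone rate trend", {
  d <- gen_rbale_dataset("switching", n_batches = 16,
                         noise = noise_model(cv = 0.02), seed = 3)
  fit <- fit_rbale(d$ts, d$events, n_starts = 5, seed = 3)
  est <- fit$per_batch$mu_est
  expect_equal(est, d$truth$mu_true, tolerance = 0.05)
  expect_true(all(diff(est) > -0.01))  # monotone up to noise
  expect_equal(est[1], 0.085, tolerance = 0.05 * 0.085 / est[1])
  expect_equal(est[16], 0.21, tolerance = 0.05)
})

test_that("estimator bias shrinks as the noise level drops", {
  mae <- vapply(c(0.02, 0.005, 0), function(cv) {
    d <- gen_rbale_dataset("constant", n_batches = 8,
                           noise = noise_model(cv = cv), seed = 11)
    fit <- fit_rbale(d$ts, d$events, n_starts = 3, seed = 11)
    mean(abs(fit$per_batch$mu_est - 0.41))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 1e-7)
})

test_that("the best objective never worsens with more starts", {
  d <- gen_rbale_dataset("constant", n_batches = 4,
                         noise = noise_model(cv = 0.02), seed = 6)
  objs <- vapply(c(1, 3, 6), function(ns) {
    fit_rbale(d$ts, d$events, n_starts = ns, seed = 6)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("explicit batch exclusion masks batches from the fit", {
  d <- gen_rbale_dataset("constant", n_batches = 5,
                         noise = noise_model(cv = 0), seed = 1)
  fit <- fit_rbale(d$ts, d$events, exclude_batches = 1L, n_starts = 2)
  expect_false(1L %in% fit$per_batch$batch)
  expect_equal(nrow(fit$per_batch), 4)
  expect_equal(fit$per_batch$mu_est, rep(0.41, 4), tolerance = 1e-6)
})

test_that("tidy and glance return well-formed summaries", {
  d <- gen_rbale_dataset("constant", n_batches = 3,
                         noise = noise_model(cv = 0), seed = 1)
  fit <- fit_rbale(d$ts, d$events, n_starts = 2)
  td <- tidy(fit)
  expect_setequal(td$term, c("mu_1", "mu_2", "mu_3", "f_dil", "X0"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_batches, 3)
})
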