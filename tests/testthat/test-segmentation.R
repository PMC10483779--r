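test_that("segmentation yields one blank-corrected slice per batch", {
  d <- gen_rbale_dataset("constant", n_batches = 16,
                         noise = noise_model(cv = 0), seed = 1)
  sl <- segment_and_normalize(d$ts, d$events)
  expect_equal(length(unique(sl$batch)), 16)
  starts <- vapply(split(sl, sl$batch), function(s) s$bs[which.min(s$time_h)],
                   numeric(1))
  # continuing batches start near threshold / f_dil (temper growth and grid
  # quantization push the value slightly above 60/17)
  expect_true(all(starts[-1] >= 60 / 17 - 1e-9))
  expect_true(all(starts[-1] <= 60 / 17 * exp(0.41 * 0.5)))
})

test_that("transfer detection reproduces the logged transfer times", {
  d <- gen_rbale_dataset("constant", n_batches = 8,
                         noise = noise_model(cv = 0.02), seed = 4)
  sl_log <- segment_and_normalize(d$ts, d$events)
  sl_det <- segment_and_normalize(d$ts)
  expect_equal(length(unique(sl_det$batch)), 8)
  t_log <- vapply(split(sl_log$time_h, sl_log$batch), min, numeric(1))
  t_det <- vapply(split(sl_det$time_h, sl_det$batch), min, numeric(1))
  expect_true(all(abs(unname(t_log) - unname(t_det)) <= 0.25 + 1e-9))
})

test_that("slices with too few points are excluded with a warning", {
  ts <- tibble::tibble(well = rep(c("A1", "A2"), each = 11),
                       time_h = rep(seq(0, 2.5, by = 0.25), 2),
                       value = 2)
  ev <- tibble::tibble(time_h = c(0, 0.25, 0.75, 0.75, 1.0, 2.5),
                       kind = c("dispense_medium", "inoculate", "harvest",
                                "dispense_medium", "inoculate", "harvest"),
                       source = c(NA, NA, "A1", NA, "A1", "A2"),
                       dest = c("A1", "A1", NA, "A2", "A2", NA),
                       batch = c(1L, 1L, 1L, 2L, 2L, 2L), group = "A")
  # batch 1 spans only three cycles and must be dropped
  expect_warning(sl <- segment_and_normalize(ts, ev, min_points = 4),
                 "excluded")
  expect_equal(unique(sl$batch), 2L)
})

test_that("log-linear slopes are exact on clean exponentials", {
  tt <- seq(0, 5, by = 0.25)
  sl <- tibble::tibble(group = "A", batch = 1L, well = "A1", time_h = tt,
                       bs = 3.5 * exp(0.2 * tt), blank = 0)
  expect_equal(loglinear_mu(sl)$mu_hat, 0.2, tolerance = 1e-9)
  # constant signal: zero slope
  sl0 <- tibble::tibble(group = "A", batch = 1L, well = "A1", time_h = tt,
                        bs = 5, blank = 0)
  expect_equal(loglinear_mu(sl0)$mu_hat, 0)
  # non-positive values reject the slice
  slneg <- tibble::tibble(group = "A", batch = 1L, well = "A1",
                          time_h = c(0, 1, 2), bs = c(1, -1, 2), blank = 0)
  expect_warning(out <- loglinear_mu(slneg), "non-positive")
  expect_equal(nrow(out), 0)
})
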