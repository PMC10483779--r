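test_that("noise-free datasets are exactly reproduced by the forward model", {
  d <- gen_rbale_dataset("constant", n_batches = 4,
                         noise = noise_model(cv = 0), seed = 1)
  sl <- segment_and_normalize(d$ts, d$events)
  mu <- loglinear_mu(sl)
  expect_equal(mu$mu_hat, rep(0.41, 4), tolerance = 1e-9)
  # blank readings carry exactly the configured blank
  blanks <- d$ts$value[d$ts$time_h %in% d$events$time_h[
    d$events$kind == "dispense_medium"]]
  expect_true(all(abs(unique(sl$blank) - d$truth$blank_bs) < 1e-12))
})

test_that("identical seeds give identical files, different seeds differ", {
  d1 <- gen_rbale_dataset("constant", n_batches = 3, seed = 99)
  d2 <- gen_rbale_dataset("constant", n_batches = 3, seed = 99)
  d3 <- gen_rbale_dataset("constant", n_batches = 3, seed = 100)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_fixtures(d1, dir1); write_fixtures(d2, dir2)
  for (f in c("timeseries.csv", "events.csv", "layout.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_false(identical(d1$ts$value, d3$ts$value))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("empirical noise CV matches the configured CV", {
  cv <- 0.05
  d <- gen_rbale_dataset("constant", n_batches = 16,
                         noise = noise_model(cv = cv), seed = 5)
  d0 <- gen_rbale_dataset("constant", n_batches = 16,
                          noise = noise_model(cv = 0), seed = 5)
  culture <- d0$ts$value > 3  # exclude blank-only readings
  ratio <- d$ts$value[culture] / d0$ts$value[culture]
  expect_gt(sum(culture), 400)
  expect_equal(stats::sd(ratio), cv, tolerance = 0.1 * cv / stats::sd(ratio))
  expect_equal(mean(ratio), 1, tolerance = 0.01)
})

test_that("switching scenario carries the stepwise-increasing rate schedule", {
  sched <- etoh_r3_schedule(16)
  expect_equal(sched[1:2], c(0.085, 0.085))
  expect_equal(sched[5], 0.16)
  expect_equal(sched[10:16], rep(0.21, 7))
  expect_true(all(diff(sched) >= 0))
  d <- gen_rbale_dataset("switching", n_batches = 16,
                         noise = noise_model(cv = 0), seed = 1)
  expect_equal(d$truth$mu_true, sched, tolerance = 1e-9)
})

test_that("noise-free bioreactor observations lie on the Monod solution", {
  d <- gen_bioreactor_dataset(noise = noise_model(cv = 0), seed = 1)
  expect_equal(length(unique(d$obs$reactor)), 4)
  p <- d$truth$params
  for (r in 1:4) {
    obs <- d$obs[d$obs$reactor == paste0("R", r), ]
    sim <- simulate_monod_batch(p, replicate = r, grid = obs$time_h)
    expect_equal(obs$cdw_gL, sim$biomass_gL, tolerance = 1e-9)
    expect_equal(mM_to_gL(obs$ethanol_mM), sim$substrate_gL, tolerance = 1e-9)
    expect_true(all(diff(obs$ethanol_mM) <= 1e-9))  # non-increasing
  }
  # replicates share globals but differ in their initial conditions
  expect_equal(nrow(unique(p$locals)), 4)
})

test_that("fixture round trips are lossless and carry the full ground truth", {
  d <- gen_rbale_dataset("switching", n_batches = 4, seed = 3)
  dir <- tempfile()
  write_fixtures(d, dir)
  fx <- read_fixtures(dir)
  expect_equal(as.data.frame(fx$ts), as.data.frame(d$ts))
  expect_equal(as.data.frame(fx$events), as.data.frame(d$events))
  expect_setequal(c("scenario", "mu", "f_dil", "X0", "blank_bs", "mu_true",
                    "transfer_times", "noise", "seed", "threshold_bs",
                    "cycle_min"),
                  setdiff(names(fx$truth), "type"))
  unlink(dir, recursive = TRUE)

  db <- gen_bioreactor_dataset(seed = 2)
  dirb <- tempfile()
  write_fixtures(db, dirb)
  fb <- read_fixtures(dirb)
  expect_equal(as.data.frame(fb$obs), as.data.frame(db$obs))
  expect_equal(fb$truth$Y_XS, 0.45)
  unlink(dirb, recursive = TRUE)
})

test_that("the fan-out layout fixture alternates media across rows", {
  dir <- tempfile()
  dir.create(dir)
  p0 <- file.path(dir, "layout.csv")
  write_layout(plate_layout_fanout(), p0)
  lay <- read_layout(p0)
  med_by_row <- tapply(lay$medium, substr(lay$well, 1, 1), unique)
  expect_equal(as.character(med_by_row[c("A", "C", "E")]),
               rep("glucose_55mM", 3))
  expect_equal(as.character(med_by_row[c("B", "D", "F")]),
               rep("ethanol_428mM", 3))
})
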