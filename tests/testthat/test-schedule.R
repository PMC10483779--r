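test_that("capacity arithmetic matches the plate geometry", {
  cap <- plan_capacity(8, 6, recycle = FALSE, gens_per_batch = 3)
  expect_equal(cap$batches_per_run, 8)
  expect_equal(cap$total_generations, 144)
  cap_r <- plan_capacity(8, 6, recycle = TRUE)
  expect_true(is.infinite(cap_r$batches_per_run))
  expect_true(is.infinite(cap_r$total_generations))
  cap1 <- plan_capacity(1, 1, recycle = FALSE, gens_per_batch = 2.5)
  expect_equal(cap1$batches_per_run, 1)
  expect_equal(cap1$total_generations, 2.5)
  expect_error(plan_capacity(0, 6), "at least one")
})

test_that("a batch triggers at the first cycle at or after the threshold", {
  sch <- run_schedule(plate_layout(n_rows = 1),
                      growth = list(A = rbale_params(mu = 0.41, X0 = 8)),
                      max_batches = 1)
  b <- sch$batches
  # growth 8 -> 60 at 0.41 1/h needs ln(7.5)/0.41 = 4.91 h; snaps to 5.0 h
  expect_equal(b$duration_h, ceiling(log(60 / 8) / 0.41 / 0.25) * 0.25)
  expect_equal(b$duration_h, 5.0)
  expect_gte(b$bs_end, 60)
  expect_lte(b$bs_end, 60 * exp(0.41 * 0.25) + 1e-9)  # <= one cycle late
})

test_that("six groups of sixteen batches give 96 records and wrap around", {
  sch <- run_schedule(plate_layout(), growth = six_group_growth(),
                      max_batches = 16)
  expect_equal(nrow(sch$batches), 96)
  a <- sch$batches[sch$batches$group == "A", ]
  expect_equal(a$well[a$batch == 9], "A1")   # wrap to the first well
  expect_equal(a$well[a$batch == 16], "A8")
  # one trigger and one inoculation per batch
  ev <- sch$events
  trig <- ev[ev$kind == "trigger", ]
  ino <- ev[ev$kind == "inoculate", ]
  expect_equal(nrow(trig), 96)
  expect_equal(nrow(ino), 96)
  expect_false(is.unsorted(ev$time_h))
  expect_equal(nrow(validate_schedule(ev)), 0)
})

test_that("without recycling a group saturates at its well count", {
  sch <- run_schedule(plate_layout(n_rows = 1),
                      growth = list(A = rbale_params(mu = 0.41)),
                      max_batches = 12, recycle = FALSE)
  expect_equal(nrow(sch$batches), 8)
  sch_r <- run_schedule(plate_layout(n_rows = 1),
                        growth = list(A = rbale_params(mu = 0.41)),
                        max_batches = 12, recycle = TRUE)
  expect_equal(nrow(sch_r$batches), 12)
})

test_that("steady-state batch generations stay within one cycle of log2(f_dil)", {
  sch <- run_schedule(plate_layout(n_rows = 1),
                      growth = list(A = rbale_params(mu = 0.41)),
                      max_batches = 10)
  g <- sch$batches$generations
  # a continuing batch spans log2(f_dil) doublings up to grid quantization of
  # the trigger on both ends and one tempering cycle of extra growth
  slack <- 2 * 0.41 * 0.25 / log(2)
  expect_true(all(g[-1] >= log2(17) - slack))
  expect_true(all(g[-1] <= log2(17) + slack))
  # cumulative generations are the sum of per-batch log2 fold-changes
  expect_equal(sum(g), sum(generations_between(sch$batches$bs_start,
                                               sch$batches$bs_end)))
})

test_that("schedule validation flags constructed violations", {
  base <- run_schedule(plate_layout(n_rows = 1),
                       growth = list(A = rbale_params(mu = 0.41)),
                       max_batches = 2)
  expect_equal(nrow(validate_schedule(base$events)), 0)
  # reuse of a washed well after only ~1 h
  ev <- tibble::tibble(
    time_h = c(0, 0.25, 5, 5, 5, 6, 6.25),
    kind = c("dispense_medium", "inoculate", "trigger", "harvest", "wash",
             "dispense_medium", "inoculate"),
    source = c(NA, NA, "A1", "A1", "A1", NA, NA),
    dest = c("A1", "A1", NA, NA, NA, "A1", "A1"),
    batch = c(1L, 1L, 1L, 1L, 1L, 2L, 2L), group = "A")
  v <- validate_schedule(ev, trigger_config(drying_time_h = 40))
  expect_equal(v$type, "drying")
  # two concurrent batches in one well
  ev2 <- tibble::tibble(
    time_h = c(0, 0.25, 2, 2.25),
    kind = c("dispense_medium", "inoculate", "dispense_medium", "inoculate"),
    source = NA_character_, dest = "A3",
    batch = c(1L, 1L, 2L, 2L), group = "A")
  v2 <- validate_schedule(ev2)
  expect_true("occupancy" %in% v2$type)
  # inoculation without a prior dispense
  ev3 <- tibble::tibble(time_h = 1, kind = "inoculate", source = NA_character_,
                        dest = "B1", batch = 1L, group = "B")
  expect_true("inoculation" %in% validate_schedule(ev3)$type)
})

test_that("drying-time pressure raises warnings, not errors, by default", {
  w <- testthat::capture_warnings(
    sch <- run_schedule(plate_layout(n_rows = 1, n_cols = 2),
                        growth = list(A = rbale_params(mu = 0.41)),
                        max_batches = 4))
  expect_true(any(grepl("drying", w)))
  expect_equal(nrow(sch$batches), 4)  # the run itself completes
  expect_error(
    suppressWarnings(run_schedule(plate_layout(n_rows = 1, n_cols = 2),
                 growth = list(A = rbale_params(mu = 0.41)),
                 max_batches = 4, on_drying_violation = "error")),
    "drying")
})

test_that("fan-out branches are always fed by the concurrent chain batch", {
  lay <- plate_layout_fanout()
  growth <- stats::setNames(lapply(LETTERS[1:6], function(g) {
    if (g %in% c("A", "C", "E")) rbale_params(mu = rep(0.41, 8))
    else rbale_params(mu = rep(0.19, 8))
  }), LETTERS[1:6])
  sch <- run_schedule(lay, growth = growth, max_batches = 8, recycle = FALSE)
  for (branch in c("B", "D", "F")) {
    feeder <- c(B = "A", D = "C", F = "E")[[branch]]
    ino <- sch$events[sch$events$kind == "inoculate" &
                        sch$events$group == branch, ]
    expect_equal(nrow(ino), 8)
    expect_true(all(substr(ino$source, 1, 1) == feeder))
    # inoculated at the feeder's transfer timestamp, batch by batch
    feeder_harv <- sch$events[sch$events$kind == "harvest" &
                                sch$events$group == feeder, ]
    expect_equal(ino$time_h, feeder_harv$time_h[order(feeder_harv$batch)])
  }
  # ethanol rows carry ethanol medium
  expect_true(all(lay$medium[lay$group %in% c("B", "D", "F")] == "ethanol_428mM"))
})

test_that("a pause delays triggering and saturates growth", {
  sch <- run_schedule(plate_layout(n_rows = 1),
                      growth = list(A = rbale_params(mu = 0.41)),
                      max_batches = 2,
                      pause = list(start_h = 4, duration_h = 6, plateau_bs = 70))
  b1 <- sch$batches[1, ]
  expect_gte(b1$t_end, 10)          # trigger deferred past the pause
  expect_lte(b1$bs_end, 70 + 1e-9)  # growth saturated at the plateau
})
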