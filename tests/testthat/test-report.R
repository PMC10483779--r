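test_that("the capacity command writes a complete, reproducible report", {
  out <- tempfile()
  cap <- rbale_run("capacity",
                   list(wells_per_group = 8, groups = 6, recycle = FALSE,
                        gens_per_batch = 3), out)
  expect_equal(cap$total_generations, 144)
  expect_true(all(file.exists(file.path(out, c("capacity.csv", "config.yaml",
                                               "run.log")))))
  cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
  expect_equal(cfg$command, "capacity")
  expect_equal(cfg$wells_per_group, 8)
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("config_hash", log)))
  expect_true(any(grepl("seed", log)))
  unlink(out, recursive = TRUE)
})

test_that("unknown configuration keys are rejected before any output", {
  out <- tempfile()
  expect_error(rbale_run("capacity", list(wellz = 8), out), "wellz")
  expect_false(dir.exists(out))
})

test_that("simulate then fit round trips through the pipeline interface", {
  simdir <- tempfile(); fitdir <- tempfile()
  rbale_run("simulate-rbale",
            list(scenario = "constant", n_batches = 5, cv = 0.02, seed = 4),
            simdir)
  fit <- rbale_run("fit-rbale", list(input = simdir, n_starts = 3, seed = 4),
                   fitdir)
  expect_true(fit$converged)
  br <- readr::read_csv(file.path(fitdir, "batch_rates.csv"),
                        col_types = readr::cols())
  expect_equal(names(br), c("group", "batch", "mu_est", "ci_lo", "ci_hi",
                            "n_points"))
  expect_equal(nrow(br), 5)
  expect_equal(br$mu_est, rep(0.41, 5), tolerance = 0.05)
  expect_true(file.exists(file.path(fitdir, "fit.json")))
  unlink(c(simdir, fitdir), recursive = TRUE)
})

test_that("a summary of a six-by-sixteen simulation lists 96 batches", {
  dir <- tempfile(); dir.create(dir)
  sch <- run_schedule(plate_layout(), growth = six_group_growth(),
                      max_batches = 16)
  write_events(sch$events, file.path(dir, "events.csv"))
  s <- rbale_report(dir)
  expect_equal(s$value[s$name == "n_batches"], 96)
  expect_equal(s$value[s$name == "n_groups"], 6)
  # idempotent: byte-identical on a second run
  first <- readLines(file.path(dir, "summary.csv"))
  firstj <- readLines(file.path(dir, "summary.json"))
  rbale_report(dir)
  expect_identical(readLines(file.path(dir, "summary.csv")), first)
  expect_identical(readLines(file.path(dir, "summary.json")), firstj)
  unlink(dir, recursive = TRUE)
})

test_that("reporting an empty directory lists the missing artifacts", {
  dir <- tempfile(); dir.create(dir)
  expect_error(rbale_report(dir), "events.csv")
  unlink(dir, recursive = TRUE)
})

test_that("the command-line interface parses flags and signals failure", {
  out <- tempfile()
  status <- rbale_cli(c("capacity", "--wells_per_group", "8", "--groups", "6",
                        "--gens_per_batch", "3", "--recycle", "false",
                        "--out", out))
  expect_equal(status, 0L)
  cap <- readr::read_csv(file.path(out, "capacity.csv"),
                         col_types = readr::cols())
  expect_equal(cap$total_generations, 144)
  unlink(out, recursive = TRUE)

  out2 <- tempfile()
  expect_message(bad <- rbale_cli(c("capacity", "--bogus_flag", "1",
                                    "--out", out2)), "bogus_flag")
  expect_equal(bad, 1L)
  expect_false(dir.exists(out2))   # no partial outputs
  expect_message(none <- rbale_cli(character(0)), "usage")
  expect_equal(none, 1L)
})

test_that("config files are honoured with flag precedence", {
  cfgfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(wells_per_group = 4, groups = 2, gens_per_batch = 3),
                   cfgfile)
  out <- tempfile()
  rbale_cli(c("capacity", "--config", cfgfile, "--groups", "6", "--out", out))
  cap <- readr::read_csv(file.path(out, "capacity.csv"),
                         col_types = readr::cols())
  expect_equal(cap$n_groups, 6)          # flag wins
  expect_equal(cap$wells_per_group, 4)   # file value kept
  unlink(out, recursive = TRUE)
})
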