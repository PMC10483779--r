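#' Measurement-noise model for synthetic datasets
#'
#' Multiplicative Gaussian noise (value scaled by `1 + cv * z`) is the
#' default, reflecting the roughly constant relative repeatability of
#' scattered-light biomass signals; additive Gaussian noise with a fixed SD
#' is available for detector-limited observables.
#'
#' @param kind `"multiplicative"` or `"additive"`.
#' @param cv Coefficient of variation (multiplicative kind), >= 0.
#' @param sd Standard deviation (additive kind), >= 0.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative", "additive"), cv = 0.02,
                        sd = 0) {
  kind <- match.arg(kind)
  stopifnot(cv >= 0, sd >= 0)
  structure(list(kind = kind, cv = cv, sd = sd), class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (noise$kind == "multiplicative") {
    if (noise$cv == 0) return(values)
    values * (1 + noise$cv * rnorm(length(values)))
  } else {
    if (noise$sd == 0) return(values)
    values + noise$sd * rnorm(length(values))
  }
}

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Stepwise growth-rate schedule of an evolving ethanol culture
#'
#' A 16-batch default emulating the batch-to-batch rise of the population
#' growth rate seen when a faster mutant takes over on ethanol: 0.085 1/h
#' for the first two batches, a ramp to 0.16 1/h by batch 5, a further ramp
#' to 0.21 1/h by batch 10, then constant. Intermediate batches are linear
#' interpolations between those anchors.
#'
#' @param n_batches Number of batches.
#' @return Numeric vector of per-batch growth rates (1/h).
#' @examples
#' etoh_r3_schedule(16)
#' @export
etoh_r3_schedule <- function(n_batches = 16) {
  stats::approx(x = c(1, 2, 5, 10), y = c(0.085, 0.085, 0.16, 0.21),
                xout = seq_len(n_batches), rule = 2)$y
}

#' Generate a synthetic repetitive-batch backscatter dataset
#'
#' Produces everything the estimation stage consumes: a long-format
#' backscatter time series on the 15-min measurement grid (raw signal =
#' per-well blank + calibrated biomass, optionally noised), the true event
#' log, the plate layout, and the ground-truth record for recovery tests.
#' Trajectories come from [run_schedule()] driving the piecewise-exponential
#' or competition model, so noise-free datasets are exactly reproduced by
#' the forward models.
#'
#' Scenarios: `"constant"` (wild-type glucose validation, mu = 0.41 1/h),
#' `"switching"` (evolving ethanol culture, [etoh_r3_schedule()]),
#' `"competition"` (explicit wild-type/mutant mixture). Defaults start the
#' first batch at backscatter ~8 (inoculation to OD 0.2) with trigger
#' threshold 60 and dilution factor 17.
#'
#' @param scenario One of `"constant"`, `"switching"`, `"competition"`.
#' @param params Optional [rbale_params()] / [competition_params()]
#'   overriding the scenario default.
#' @param n_batches Number of batches (default 16).
#' @param noise A [noise_model()]; `cv = 0` gives noise-free data.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param blank_bs Per-well blank backscatter added to the raw signal.
#' @param trigger A [trigger_config()].
#' @param n_wells Wells in the (single-group) layout.
#'
#' @return An object of class `rbale_dataset`: list with tibbles `ts`
#'   (`well`, `time_h`, `filterset`, `value`), `events`, `layout`, `batches`
#'   (true per-batch records) and a `truth` list (scenario, parameters,
#'   per-batch true rates, blank, noise, seed).
#' @examples
#' d <- gen_rbale_dataset("constant", n_batches = 4, seed = 1)
#' head(d$ts)
#' @export
gen_rbale_dataset <- function(scenario = c("constant", "switching", "competition"),
                              params = NULL, n_batches = 16,
                              noise = noise_model(cv = 0.02), seed = 1,
                              blank_bs = 2, trigger = trigger_config(),
                              n_wells = 8) {
  scenario <- match.arg(scenario)
  if (is.null(params)) {
    params <- switch(scenario,
      constant = rbale_params(mu = rep(0.41, n_batches), f_dil = 17, X0 = 8),
      switching = rbale_params(mu = etoh_r3_schedule(n_batches), f_dil = 17,
                               X0 = 8),
      competition = competition_params(mu_wt = 0.085, mu_evo = 0.21,
                                       emergence_batch = 2L,
                                       initial_fraction = 1e-6,
                                       n_batches = n_batches, f_dil = 17,
                                       X0 = 8))
  }
  layout <- plate_layout(n_rows = 1, n_cols = n_wells,
                         media = if (scenario == "constant") "glucose_111mM"
                                 else "ethanol_428mM")
  sched <- run_schedule(layout, trigger = trigger,
                        growth = list(A = params), max_batches = n_batches,
                        recycle = TRUE)
  meas <- sched$measurements
  raw <- meas$backscatter + blank_bs
  noised <- with_local_seed(seed, apply_noise(raw, noise))
  ts <- tibble::tibble(well = meas$well, time_h = meas$time_h,
                       filterset = "BS", value = noised)
  ts <- ts[order(ts$time_h, ts$well), ]
  out <- list(
    ts = ts, events = sched$events, layout = layout, batches = sched$batches,
    schedule = sched,
    truth = list(scenario = scenario, params = params,
                 mu_true = sched$batches$apparent_mu,
                 transfer_times = sched$batches$t_start,
                 f_dil = params$f_dil, X0 = params$X0,
                 blank_bs = blank_bs, noise = noise, seed = seed,
                 trigger = trigger))
  class(out) <- "rbale_dataset"
  out
}

#' @export
print.rbale_dataset <- function(x, ...) {
  cat(sprintf("<rbale_dataset> scenario '%s': %d batches, %d measurements, cv = %g, seed = %s\n",
              x$truth$scenario, nrow(x$batches), nrow(x$ts),
              x$truth$noise$cv, format(x$truth$seed)))
  invisible(x)
}

#' Generate synthetic replicate bioreactor datasets
#'
#' Emulates parallel lab-scale batch reactors on ethanol sampled offline
#' every two hours for cell dry weight and ethanol concentration. All
#' reactors share the global Monod kinetics; each has its own initial
#' conditions (inoculation to OD 3.5 via a configurable OD-to-CDW factor,
#' 428 mM ethanol), deterministically jittered a few percent per reactor to
#' emulate separate inoculations. Observables carry independent
#' multiplicative noise.
#'
#' @param params Optional [monod_params()] ground truth; the default uses
#'   mu_max = 0.15 1/h, K_S = 0.01 g/L, Y_XS = 0.45 g/g.
#' @param n_reactors Number of replicate reactors (default 4).
#' @param sample_interval_h Offline sampling interval (default 2 h).
#' @param t_end_h Cultivation horizon (h).
#' @param noise A [noise_model()] (default 3% multiplicative CV).
#' @param seed Integer seed.
#' @param od_to_cdw OD-to-CDW conversion factor (g CDW/L per OD unit,
#'   default 0.25; instrument-specific, set explicitly when known).
#' @param local_jitter Relative spread of per-reactor initial conditions.
#'
#' @return An object of class `bioreactor_dataset`: list with tibble `obs`
#'   (`reactor`, `time_h`, `cdw_gL`, `ethanol_mM`) and a `truth` list
#'   holding the [monod_params()] used.
#' @export
gen_bioreactor_dataset <- function(params = NULL, n_reactors = 4,
                                   sample_interval_h = 2, t_end_h = 24,
                                   noise = noise_model(cv = 0.03), seed = 1,
                                   od_to_cdw = 0.25, local_jitter = 0.03) {
  if (is.null(params)) {
    base_X0 <- 3.5 * od_to_cdw
    base_S0 <- mM_to_gL(428)
    # deterministic alternating jitter so replicates differ in locals only
    j <- local_jitter * rep_len(c(-1, 0.5, 1, -0.5), n_reactors)
    params <- monod_params(mu_max = 0.15, K_S = 0.01, Y_XS = 0.45,
                           locals = tibble::tibble(X0 = base_X0 * (1 + j),
                                                   S0 = base_S0 * (1 - j)))
  }
  if (nrow(params$locals) != n_reactors) {
    stop("`params$locals` must have one row per reactor", call. = FALSE)
  }
  grid <- seq(0, t_end_h, by = sample_interval_h)
  sims <- purrr::map(seq_len(n_reactors), function(r) {
    sim <- simulate_monod_batch(params, replicate = r, grid = grid)
    tibble::tibble(reactor = paste0("R", r), time_h = sim$time_h,
                   cdw_gL = sim$biomass_gL,
                   ethanol_mM = gL_to_mM(sim$substrate_gL))
  })
  obs <- dplyr::bind_rows(sims)
  obs <- with_local_seed(seed, {
    obs$cdw_gL <- apply_noise(obs$cdw_gL, noise)
    obs$ethanol_mM <- apply_noise(obs$ethanol_mM, noise)
    obs
  })
  out <- list(obs = obs,
              truth = list(params = params, noise = noise, seed = seed,
                           sample_interval_h = sample_interval_h,
                           od_to_cdw = od_to_cdw))
  class(out) <- "bioreactor_dataset"
  out
}

#' @export
print.bioreactor_dataset <- function(x, ...) {
  cat(sprintf("<bioreactor_dataset> %d reactors, %d observations, cv = %g\n",
              length(unique(x$obs$reactor)), nrow(x$obs), x$truth$noise$cv))
  invisible(x)
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Writes the external CSV dialects (long time series `well,time_h,
#' filterset,value`; event log `time_h,kind,source,dest,batch,group`; layout
#' `well,group,medium,role`; bioreactor table `reactor,time_h,cdw_gL,
#' ethanol_mM`) plus a `truth.json` carrying every parameter needed to
#' re-simulate the dataset. [read_fixtures()] restores the tables.
#'
#' @param dataset An `rbale_dataset` or `bioreactor_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(dataset, "rbale_dataset")) {
    readr::write_csv(dataset$ts, file.path(dir, "timeseries.csv"))
    write_events(dataset$events, file.path(dir, "events.csv"))
    write_layout(dataset$layout, file.path(dir, "layout.csv"))
    truth <- dataset$truth
    json <- list(
      type = "rbale", scenario = truth$scenario,
      mu = if (inherits(truth$params, "rbale_params")) truth$params$mu else NULL,
      competition = if (inherits(truth$params, "competition_params"))
        truth$params[c("mu_wt", "mu_evo", "emergence_batch",
                       "initial_fraction", "n_batches")] else NULL,
      f_dil = truth$f_dil, X0 = truth$X0, blank_bs = truth$blank_bs,
      mu_true = truth$mu_true, transfer_times = truth$transfer_times,
      noise = unclass(truth$noise), seed = truth$seed,
      threshold_bs = truth$trigger$threshold_bs,
      cycle_min = truth$trigger$cycle_min)
  } else if (inherits(dataset, "bioreactor_dataset")) {
    readr::write_csv(dataset$obs, file.path(dir, "bioreactor.csv"))
    p <- dataset$truth$params
    json <- list(type = "bioreactor", mu_max = p$mu_max, K_S = p$K_S,
                 Y_XS = p$Y_XS, locals = p$locals,
                 noise = unclass(dataset$truth$noise),
                 seed = dataset$truth$seed,
                 sample_interval_h = dataset$truth$sample_interval_h,
                 od_to_cdw = dataset$truth$od_to_cdw)
  } else {
    stop("unknown dataset type", call. = FALSE)
  }
  json <- json[!vapply(json, is.null, logical(1))]
  jsonlite::write_json(json, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (identical(truth$type, "bioreactor")) {
    obs <- readr::read_csv(file.path(dir, "bioreactor.csv"),
                           col_types = readr::cols(
                             reactor = readr::col_character(),
                             time_h = readr::col_double(),
                             cdw_gL = readr::col_double(),
                             ethanol_mM = readr::col_double()))
    return(list(obs = obs, truth = truth))
  }
  ts <- readr::read_csv(file.path(dir, "timeseries.csv"),
                        col_types = readr::cols(
                          well = readr::col_character(),
                          time_h = readr::col_double(),
                          filterset = readr::col_character(),
                          value = readr::col_double()))
  list(ts = ts,
       events = read_events(file.path(dir, "events.csv")),
       layout = read_layout(file.path(dir, "layout.csv")),
       truth = truth)
}
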