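#' Trigger and liquid-handling configuration
#'
#' Settings of the threshold-triggered transfer workflow. The backscatter
#' threshold is an absolute value fixed before the run (in practice 60% of
#' the expected final signal); the simulator never infers it from data.
#' Measurements happen every `cycle_min` minutes and all events snap to
#' this grid. After a trigger, fresh medium is dispensed into the next well
#' and tempered for `temper_cycles` cycles before the triggering well is
#' harvested and `transfer_volume_ul` of it is pipetted into the
#' `well_volume_ul` of tempered medium. The harvested well is washed
#' (`wash_steps` steps of `wash_volume_ul`) and must then idle
#' `drying_time_h` hours before reuse.
#'
#' @param threshold_bs Absolute blank-corrected backscatter trigger (> 0).
#' @param cycle_min Measurement period in minutes.
#' @param temper_cycles Tempering delay in measurement cycles.
#' @param transfer_volume_ul,well_volume_ul Inoculum and culture volumes
#'   (microlitres); their ratio `(well + transfer)/transfer` is the nominal
#'   dilution factor (17 for 50 into 800).
#' @param wash_steps,wash_volume_ul Washing procedure.
#' @param drying_time_h Minimum idle time before a washed well is reused (h).
#'
#' @return An object of class `trigger_config`.
#' @export
trigger_config <- function(threshold_bs = 60, cycle_min = 15, temper_cycles = 1,
                           transfer_volume_ul = 50, well_volume_ul = 800,
                           wash_steps = 2, wash_volume_ul = 900,
                           drying_time_h = 40) {
  stopifnot(threshold_bs > 0, cycle_min > 0, temper_cycles >= 0,
            transfer_volume_ul > 0, well_volume_ul > 0,
            wash_steps >= 0, wash_volume_ul > 0, drying_time_h >= 0)
  structure(list(threshold_bs = threshold_bs, cycle_min = cycle_min,
                 temper_cycles = temper_cycles,
                 transfer_volume_ul = transfer_volume_ul,
                 well_volume_ul = well_volume_ul, wash_steps = wash_steps,
                 wash_volume_ul = wash_volume_ul,
                 drying_time_h = drying_time_h),
            class = "trigger_config")
}

#' @export
print.trigger_config <- function(x, ...) {
  cat(sprintf("<trigger_config> threshold %g BS, %g-min cycles, %g uL -> %g uL (f_dil %.3g), drying %g h\n",
              x$threshold_bs, x$cycle_min, x$transfer_volume_ul,
              x$well_volume_ul, nominal_f_dil(x), x$drying_time_h))
  invisible(x)
}

#' Nominal dilution factor from pipetting volumes
#' @param trigger A [trigger_config()] object.
#' @return `(well_volume + transfer_volume) / transfer_volume`.
#' @export
nominal_f_dil <- function(trigger = trigger_config()) {
  (trigger$well_volume_ul + trigger$transfer_volume_ul) / trigger$transfer_volume_ul
}

#' Capacity of a repetitive-batch experiment
#'
#' Without well recycling a group of `wells_per_group` wells supports at
#' most `wells_per_group` consecutive batches, so a full plate yields
#' `wells_per_group * n_groups * gens_per_batch` generations in total (144
#' for the standard 48-well plate at three generations per batch). With
#' recycling, washed wells are reused and both counts are unbounded.
#'
#' @param wells_per_group Wells per cultivation group.
#' @param n_groups Number of parallel groups.
#' @param recycle Logical; are wells washed, dried and reused?
#' @param gens_per_batch Generations per batch (defaults to the rounded
#'   value implied by the standard start/threshold backscatter span, see
#'   [generations_between()]).
#'
#' @return A one-row tibble with columns `wells_per_group`, `n_groups`,
#'   `recycle`, `gens_per_batch`, `batches_per_run`, `total_generations`
#'   (both `Inf` when recycling).
#' @examples
#' plan_capacity(8, 6, recycle = FALSE, gens_per_batch = 3)
#' plan_capacity(8, 6, recycle = TRUE)
#' @export
plan_capacity <- function(wells_per_group, n_groups, recycle = FALSE,
                          gens_per_batch = round(generations_between(8, 60))) {
  if (wells_per_group < 1 || n_groups < 1) {
    stop("need at least one well per group and one group", call. = FALSE)
  }
  stopifnot(gens_per_batch >= 0)
  tibble::tibble(
    wells_per_group = wells_per_group, n_groups = n_groups, recycle = recycle,
    gens_per_batch = gens_per_batch,
    batches_per_run = if (recycle) Inf else wells_per_group,
    total_generations = if (recycle) Inf else
      wells_per_group * n_groups * gens_per_batch
  )
}

event_kind_order <- c("measure", "trigger", "dispense_medium", "temper",
                      "harvest", "inoculate", "wash", "dry_complete")

#' Run the discrete-event rbALE schedule
#'
#' Simulates the threshold-triggered repetitive-batch workflow for every
#' group of a plate layout. Chain groups proceed along their wells, wrapping
#' to the first well when recycling; branch groups are inoculated from their
#' feeder's concurrent batch. Growth within a batch follows the
#' piecewise-exponential model ([rbale_params()]) or the competition model
#' ([competition_params()]); the trigger fires at the first measurement
#' cycle at or after the blank-corrected backscatter crosses the threshold,
#' fresh medium tempers for one cycle, and the transfer dilutes the culture
#' by the group's `f_dil` at the inoculation timestamp.
#'
#' @param layout A [plate_layout()] tibble.
#' @param trigger A [trigger_config()].
#' @param growth Named list mapping each group label to its
#'   [rbale_params()] or [competition_params()]. A growth-rate vector
#'   shorter than the realised batch count is extended with its last value.
#' @param max_batches Stop rule: batches per chain group.
#' @param max_time_h Stop rule: wall-clock horizon (h).
#' @param recycle Reuse wells after washing and drying (default `TRUE`).
#' @param pause Optional technical-failure emulation:
#'   `list(start_h=, duration_h=, plateau_bs=)`. While paused no trigger is
#'   evaluated and growth saturates at `plateau_bs`.
#' @param on_drying_violation `"warn"` (default) or `"error"`: reuse of a
#'   well before `drying_time_h` has elapsed since washing.
#'
#' @return An object of class `rbale_schedule`: a list with tibbles
#'   `events` (`time_h`, `kind`, `source`, `dest`, `batch`, `group`),
#'   `batches` (per-batch records with start/end backscatter, duration and
#'   generations) and `measurements` (per-well blank-corrected backscatter
#'   on the measurement grid), plus the configuration used.
#' @examples
#' sched <- run_schedule(plate_layout(n_rows = 1),
#'                       growth = list(A = rbale_params(mu = 0.41)),
#'                       max_batches = 3)
#' sched$batches
#' @export
run_schedule <- function(layout, trigger = trigger_config(), growth,
                         max_batches = 16, max_time_h = Inf, recycle = TRUE,
                         pause = NULL, on_drying_violation = c("warn", "error")) {
  stopifnot(inherits(layout, "rbale_layout") || is.data.frame(layout),
            inherits(trigger, "trigger_config"), is.list(growth))
  on_drying_violation <- match.arg(on_drying_violation)
  if (!is.finite(max_batches) && !is.finite(max_time_h)) {
    stop("at least one stop rule (`max_batches`, `max_time_h`) must be finite",
         call. = FALSE)
  }
  feeders <- layout_feeders(layout)
  groups <- names(feeders)
  missing_growth <- setdiff(groups, names(growth))
  if (length(missing_growth)) {
    stop("no growth parameters for group(s): ",
         paste(missing_growth, collapse = ", "), call. = FALSE)
  }
  dt <- trigger$cycle_min / 60
  sim <- new.env(parent = emptyenv())
  sim$events <- list(); sim$batches <- list(); sim$meas <- list()
  sim$wash_done <- list()   # well -> time washing finished
  sim$occupied_until <- list()

  chain_groups <- groups[is.na(feeders)]
  harvest_cache <- list()   # group -> tibble of feeder harvests
  for (g in sort(chain_groups)) {
    harvest_cache[[g]] <- simulate_chain_group(
      g, layout, trigger, growth[[g]], max_batches, max_time_h, recycle,
      pause, on_drying_violation, dt, sim)
  }
  for (g in sort(groups[!is.na(feeders)])) {
    simulate_branch_group(g, feeders[[g]], harvest_cache[[feeders[[g]]]],
                          layout, trigger, growth[[g]], recycle,
                          on_drying_violation, dt, sim)
  }

  events <- dplyr::bind_rows(sim$events)
  events <- events[order(events$time_h,
                         match(events$kind, event_kind_order),
                         events$group), , drop = FALSE]
  out <- list(events = tibble::as_tibble(events),
              batches = dplyr::bind_rows(sim$batches),
              measurements = dplyr::bind_rows(sim$meas),
              layout = layout, trigger = trigger, recycle = recycle)
  class(out) <- "rbale_schedule"
  out
}

#' @export
print.rbale_schedule <- function(x, ...) {
  cat(sprintf("<rbale_schedule> %d batches in %d group(s), %d events, %.1f h\n",
              nrow(x$batches), length(unique(x$batches$group)),
              nrow(x$events), max(x$events$time_h)))
  invisible(x)
}

# --- internals --------------------------------------------------------------

new_growth_state <- function(params) {
  if (inherits(params, "rbale_params")) {
    list(kind = "single", X = params$X0, mu = params$mu,
         f_dil = params$f_dil, calib = params$calib)
  } else if (inherits(params, "competition_params")) {
    wt <- params$X0; mut <- 0
    if (params$emergence_batch == 1L) {
      mut <- params$initial_fraction * wt
      wt <- wt - mut
    }
    list(kind = "comp", wt = wt, mut = mut, params = params,
         f_dil = params$f_dil, calib = params$calib)
  } else {
    stop("growth parameters must be rbale_params or competition_params",
         call. = FALSE)
  }
}

state_biomass_at <- function(state, batch, dts) {
  if (state$kind == "single") {
    mu <- state$mu[min(batch, length(state$mu))]
    state$X * exp(mu * dts)
  } else {
    p <- state$params
    state$wt * exp(p$mu_wt * dts) + state$mut * exp(p$mu_evo * dts)
  }
}

# advance state across a transfer: grow dt within batch, divide by f_dil
state_transfer <- function(state, batch, dt_grown) {
  if (state$kind == "single") {
    mu <- state$mu[min(batch, length(state$mu))]
    state$X <- state$X * exp(mu * dt_grown) / state$f_dil
  } else {
    p <- state$params
    state$wt <- state$wt * exp(p$mu_wt * dt_grown) / state$f_dil
    state$mut <- state$mut * exp(p$mu_evo * dt_grown) / state$f_dil
    if (batch + 1L == p$emergence_batch) {
      tot <- state$wt + state$mut
      state$mut <- p$initial_fraction * tot
      state$wt <- tot - state$mut
    }
  }
  state
}

in_pause <- function(t, pause) {
  !is.null(pause) && t >= pause$start_h && t < pause$start_h + pause$duration_h
}

# a culture that was growing when the pause began saturates at the plateau
# and stays there until it is harvested; later batches grow normally
cap_pause <- function(x, t, pause, plateau_x, t_inoc) {
  if (!is.null(pause) && t >= pause$start_h && t_inoc <= pause$start_h) {
    pmin(x, plateau_x)
  } else {
    x
  }
}

add_event <- function(sim, time_h, kind, source = NA_character_,
                      dest = NA_character_, batch = NA_integer_, group) {
  sim$events[[length(sim$events) + 1L]] <-
    tibble::tibble(time_h = time_h, kind = kind, source = source, dest = dest,
                   batch = as.integer(batch), group = group)
}

check_well_free <- function(sim, well, t_disp, trigger, on_drying_violation) {
  occ <- sim$occupied_until[[well]]
  if (!is.null(occ) && t_disp < occ) {
    stop(sprintf("well %s scheduled at %.2f h while occupied until %.2f h",
                 well, t_disp, occ), call. = FALSE)
  }
  wd <- sim$wash_done[[well]]
  if (!is.null(wd) && t_disp < wd + trigger$drying_time_h) {
    msg <- sprintf("well %s reused %.1f h after washing (drying time %g h)",
                   well, t_disp - wd, trigger$drying_time_h)
    if (on_drying_violation == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
}

# one batch: culture grows in `well` from X at t_inoc until threshold.
# Returns trigger time; caller handles dilution/harvest bookkeeping.
find_trigger_time <- function(state, batch, t_inoc, dt, threshold_x, pause,
                              plateau_x, max_time_h) {
  k <- 0L
  repeat {
    k <- k + 1L
    t <- t_inoc + k * dt
    if (t > max_time_h + 1e-9) return(NULL)
    if (in_pause(t, pause) && t_inoc <= pause$start_h) next
    x <- cap_pause(state_biomass_at(state, batch, t - t_inoc), t, pause,
                   plateau_x, t_inoc)
    if (x >= threshold_x - 1e-12) return(t)
    if (k > 500000L) stop("no trigger within 500000 cycles", call. = FALSE)
  }
}

record_measurements <- function(sim, state, batch, g, well, t_disp, t_inoc,
                                t_last, dt, calib, pause, plateau_x) {
  times <- seq(t_disp, t_last, by = dt)
  cult <- times >= t_inoc - 1e-9
  x <- numeric(length(times))
  dts <- times[cult] - t_inoc
  xv <- state_biomass_at(state, batch, dts)
  if (!is.null(pause) && t_inoc <= pause$start_h) {
    # once capped the culture stays at the plateau until harvest
    after <- times[cult] >= pause$start_h
    xv[after] <- pmin(xv[after], plateau_x)
  }
  x[cult] <- xv
  sim$meas[[length(sim$meas) + 1L]] <- tibble::tibble(
    well = well, group = g, batch = as.integer(batch), time_h = times,
    phase = ifelse(cult, "culture", "blank"),
    backscatter = ifelse(cult, biomass_to_bs(x, calib), 0))
}

simulate_chain_group <- function(g, layout, trigger, params, max_batches,
                                 max_time_h, recycle, pause,
                                 on_drying_violation, dt, sim) {
  wells <- layout$well[layout$group == g]
  n_w <- length(wells)
  state <- new_growth_state(params)
  threshold_x <- bs_to_biomass(trigger$threshold_bs, state$calib)
  plateau_x <- if (!is.null(pause)) {
    bs_to_biomass(pause$plateau_bs %||% (trigger$threshold_bs * 1.3),
                  state$calib)
  } else Inf
  temper_h <- trigger$temper_cycles * dt
  harvests <- list()   # feeder info for branch groups

  b <- 1L
  t_disp <- 0
  well <- wells[1L]
  add_event(sim, t_disp, "dispense_medium", dest = well, batch = b, group = g)
  t_inoc <- t_disp + temper_h
  add_event(sim, t_inoc, "inoculate", dest = well, batch = b, group = g)
  sim$occupied_until[[well]] <- Inf

  repeat {
    t_trig <- find_trigger_time(state, b, t_inoc, dt, threshold_x, pause,
                                plateau_x, max_time_h)
    if (is.null(t_trig)) {  # horizon reached mid-batch; drop unfinished batch
      sim$occupied_until[[well]] <- Inf
      break
    }
    add_event(sim, t_trig, "trigger", source = well, batch = b, group = g)
    t_harv <- t_trig + temper_h
    x_start <- state_biomass_at(state, b, 0)
    x_trig <- cap_pause(state_biomass_at(state, b, t_trig - t_inoc),
                        t_trig, pause, plateau_x, t_inoc)
    bs_start <- biomass_to_bs(x_start, state$calib)
    bs_trig <- biomass_to_bs(x_trig, state$calib)
    sim$batches[[length(sim$batches) + 1L]] <- tibble::tibble(
      group = g, batch = b, well = well, t_start = t_inoc, t_end = t_trig,
      duration_h = t_trig - t_inoc, bs_start = bs_start, bs_end = bs_trig,
      generations = generations_between(bs_start, bs_trig),
      apparent_mu = log(x_trig / x_start) / (t_trig - t_inoc))
    record_measurements(sim, state, b, g, well, t_disp, t_inoc, t_harv, dt,
                        state$calib, pause, plateau_x)
    harvests[[b]] <- tibble::tibble(batch = b, well = well, t_trig = t_trig,
                                    t_harv = t_harv,
                                    x_harv = cap_pause(
                                      state_biomass_at(state, b, t_harv - t_inoc),
                                      t_harv, pause, plateau_x, t_inoc))

    continue <- b < max_batches && (recycle || b < n_w) && t_harv <= max_time_h
    next_well <- wells[(b %% n_w) + 1L]
    if (continue) {
      add_event(sim, t_trig, "dispense_medium", dest = next_well,
                batch = b + 1L, group = g)
      add_event(sim, t_trig, "temper", dest = next_well, batch = b + 1L,
                group = g)
      check_well_free(sim, next_well, t_trig, trigger, on_drying_violation)
      sim$occupied_until[[next_well]] <- Inf
    }
    add_event(sim, t_harv, "harvest", source = well, batch = b, group = g)
    sim$occupied_until[[well]] <- t_harv
    for (w in seq_len(trigger$wash_steps)) {
      add_event(sim, t_harv, "wash", source = well, batch = b, group = g)
    }
    sim$wash_done[[well]] <- t_harv
    add_event(sim, t_harv + trigger$drying_time_h, "dry_complete",
              source = well, batch = b, group = g)
    if (!continue) break

    add_event(sim, t_harv, "inoculate", source = well, dest = next_well,
              batch = b + 1L, group = g)
    # dilution at the transfer timestamp: culture kept growing through temper
    x_pause_capped <- cap_pause(state_biomass_at(state, b, t_harv - t_inoc),
                                t_harv, pause, plateau_x, t_inoc)
    state <- state_transfer(state, b, t_harv - t_inoc)
    if (is.finite(plateau_x)) {  # transfer from a saturated culture
      if (state$kind == "single") {
        state$X <- min(state$X, x_pause_capped / state$f_dil)
      }
    }
    t_disp <- t_trig
    t_inoc <- t_harv
    well <- next_well
    b <- b + 1L
  }
  dplyr::bind_rows(harvests)
}

simulate_branch_group <- function(g, feeder, harvests, layout, trigger, params,
                                  recycle, on_drying_violation, dt, sim) {
  if (is.null(harvests) || !nrow(harvests)) return(invisible(NULL))
  wells <- layout$well[layout$group == g]
  n_w <- length(wells)
  threshold_x <- bs_to_biomass(trigger$threshold_bs,
                               if (inherits(params, "rbale_params"))
                                 params$calib else params$calib)
  temper_h <- trigger$temper_cycles * dt
  n_batches <- if (recycle) nrow(harvests) else min(nrow(harvests), n_w)
  for (b in seq_len(n_batches)) {
    h <- harvests[b, ]
    well <- wells[((b - 1L) %% n_w) + 1L]
    t_disp <- h$t_trig
    t_inoc <- h$t_harv
    add_event(sim, t_disp, "dispense_medium", dest = well, batch = b, group = g)
    add_event(sim, t_disp, "temper", dest = well, batch = b, group = g)
    check_well_free(sim, well, t_disp, trigger, on_drying_violation)
    sim$occupied_until[[well]] <- Inf
    add_event(sim, t_inoc, "inoculate", source = h$well, dest = well,
              batch = b, group = g)
    state <- new_growth_state(params)
    f_dil <- state$f_dil
    if (state$kind == "single") {
      state$X <- h$x_harv / f_dil
    } else {
      frac <- state$mut / (state$wt + state$mut)
      state$wt <- (1 - frac) * h$x_harv / f_dil
      state$mut <- frac * h$x_harv / f_dil
    }
    t_trig <- find_trigger_time(state, b, t_inoc, dt, threshold_x, NULL, Inf, Inf)
    add_event(sim, t_trig, "trigger", source = well, batch = b, group = g)
    t_harv <- t_trig + temper_h
    x_start <- state_biomass_at(state, b, 0)
    x_trig <- state_biomass_at(state, b, t_trig - t_inoc)
    bs_start <- biomass_to_bs(x_start, state$calib)
    bs_trig <- biomass_to_bs(x_trig, state$calib)
    sim$batches[[length(sim$batches) + 1L]] <- tibble::tibble(
      group = g, batch = b, well = well, t_start = t_inoc, t_end = t_trig,
      duration_h = t_trig - t_inoc, bs_start = bs_start, bs_end = bs_trig,
      generations = generations_between(bs_start, bs_trig),
      apparent_mu = log(x_trig / x_start) / (t_trig - t_inoc))
    record_measurements(sim, state, b, g, well, t_disp, t_inoc, t_harv, dt,
                        state$calib, NULL, Inf)
    add_event(sim, t_harv, "harvest", source = well, batch = b, group = g)
    sim$occupied_until[[well]] <- t_harv
    for (w in seq_len(trigger$wash_steps)) {
      add_event(sim, t_harv, "wash", source = well, batch = b, group = g)
    }
    sim$wash_done[[well]] <- t_harv
    add_event(sim, t_harv + trigger$drying_time_h, "dry_complete",
              source = well, batch = b, group = g)
  }
  invisible(NULL)
}

#' Check an event log against the workflow constraints
#'
#' Violations are returned as data, not raised as conditions: an empty
#' result means (i) no well hosts overlapping batches, (ii) every reuse of
#' a well respects the drying time, and (iii) every inoculation was preceded
#' by a medium dispense plus tempering into the destination well.
#'
#' @param events An event-log tibble (`time_h`, `kind`, `source`, `dest`,
#'   `batch`, `group`) from [run_schedule()] or read from CSV.
#' @param trigger The [trigger_config()] the log should satisfy.
#'
#' @return A tibble of violations with columns `type`, `well`, `time_h`,
#'   `detail`; zero rows if the log is consistent.
#' @export
validate_schedule <- function(events, trigger = trigger_config()) {
  stopifnot(is.data.frame(events))
  if (is.unsorted(events$time_h)) {
    stop("event log must be time-ordered", call. = FALSE)
  }
  dt <- trigger$cycle_min / 60
  viol <- list()
  push <- function(type, well, time_h, detail) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      type = type, well = well, time_h = time_h, detail = detail)
  }
  disp <- events[events$kind == "dispense_medium", ]
  harv <- events[events$kind == "harvest", ]
  wash <- events[events$kind == "wash", ]
  inoc <- events[events$kind == "inoculate", ]

  # occupancy: per well, intervals [dispense, harvest] must not overlap
  for (w in unique(disp$dest)) {
    d_t <- sort(disp$time_h[disp$dest == w])
    h_t <- sort(harv$time_h[harv$source == w])
    for (i in seq_along(d_t)) {
      if (i > 1L) {
        prev_end <- h_t[i - 1L]
        if (is.na(prev_end) || d_t[i] < prev_end - 1e-9) {
          push("occupancy", w, d_t[i],
               sprintf("dispense at %.2f h before previous batch harvested", d_t[i]))
        }
      }
    }
    if (length(h_t) < length(d_t) - 1L) {
      push("occupancy", w, d_t[length(d_t)], "more than one unharvested batch")
    }
  }
  # drying: reuse only drying_time_h after the last wash of the well
  for (w in unique(disp$dest)) {
    d_t <- sort(disp$time_h[disp$dest == w])
    w_t <- sort(wash$time_h[wash$source == w])
    for (t in d_t) {
      last_wash <- suppressWarnings(max(w_t[w_t <= t + 1e-9]))
      if (is.finite(last_wash) && t < last_wash + trigger$drying_time_h - 1e-9) {
        push("drying", w, t,
             sprintf("reused %.1f h after washing (< %g h)", t - last_wash,
                     trigger$drying_time_h))
      }
    }
  }
  # every inoculation preceded by dispense + tempering into the same well
  temper_h <- trigger$temper_cycles * dt
  for (i in seq_len(nrow(inoc))) {
    w <- inoc$dest[i]; t <- inoc$time_h[i]
    ok <- any(disp$dest == w & disp$time_h <= t - temper_h + 1e-9)
    if (!ok) {
      push("inoculation", w, t, "no prior medium dispense with tempering")
    }
  }
  if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(type = character(), well = character(),
                   time_h = numeric(), detail = character())
}

#' Read and write event logs
#'
#' External dialect: CSV with columns `time_h,kind,source,dest,batch,group`.
#' @param events Event-log tibble.
#' @param path File path.
#' @return `read_events()` returns the tibble; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events[, c("time_h", "kind", "source", "dest", "batch",
                              "group")], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_h = readr::col_double(), kind = readr::col_character(),
    source = readr::col_character(), dest = readr::col_character(),
    batch = readr::col_integer(), group = readr::col_character()))
}
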