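#' Wild-type / mutant competition trajectory
#'
#' Two subpopulations grow as independent exponentials (rates `mu_wt` and
#' `mu_evo`) and share every transfer event: both are divided by `f_dil`.
#' The mutant appears at the (post-dilution) start of `emergence_batch` as a
#' fraction `initial_fraction` of the total biomass. Because dilution acts
#' equally on both, the mutant-to-wild-type ratio grows by
#' \eqn{e^{(\mu_{evo}-\mu_{wt})\Delta t_i}} every batch, so the population's
#' apparent growth rate rises monotonically from `mu_wt` towards `mu_evo`.
#'
#' @param params A [competition_params()] object.
#' @param transfer_times Strictly increasing transfer times (h); their number
#'   must equal `params$n_batches - 1`.
#' @param grid Time grid (h).
#'
#' @return A tibble with columns `time_h`, `batch`, `biomass_wt`,
#'   `biomass_mut`, `biomass`, `backscatter`. Per-batch apparent rates are
#'   available via [competition_apparent_rates()].
#' @export
competition_trajectory <- function(params, transfer_times,
                                   grid = seq(0, max(transfer_times) + 5, by = 0.25)) {
  stopifnot(inherits(params, "competition_params"))
  transfer_times <- as.numeric(transfer_times)
  if (length(transfer_times) != params$n_batches - 1L) {
    stop("number of transfer times must equal n_batches - 1", call. = FALSE)
  }
  if (length(transfer_times) && any(diff(transfer_times) <= 0)) {
    stop("`transfer_times` must be strictly increasing", call. = FALSE)
  }
  grid <- sort(as.numeric(grid))
  st <- competition_batch_starts(params, transfer_times)
  t_open <- c(0, transfer_times)
  batch <- findInterval(grid, transfer_times) + 1L
  dt <- grid - t_open[batch]
  wt <- st$wt[batch] * exp(params$mu_wt * dt)
  mut <- st$mut[batch] * exp(params$mu_evo * dt)
  tibble::tibble(
    time_h = grid, batch = batch,
    biomass_wt = wt, biomass_mut = mut, biomass = wt + mut,
    backscatter = biomass_to_bs(wt + mut, params$calib)
  )
}

# Post-dilution WT and mutant biomass at the start of each batch
competition_batch_starts <- function(params, transfer_times) {
  n <- params$n_batches
  wt <- mut <- numeric(n)
  wt[1L] <- params$X0
  if (params$emergence_batch == 1L) {
    mut[1L] <- params$initial_fraction * params$X0
    wt[1L] <- (1 - params$initial_fraction) * params$X0
  }
  t_open <- c(0, transfer_times)
  for (i in seq_len(n - 1L)) {
    dt <- transfer_times[i] - t_open[i]
    wt[i + 1L] <- wt[i] * exp(params$mu_wt * dt) / params$f_dil
    mut[i + 1L] <- mut[i] * exp(params$mu_evo * dt) / params$f_dil
    if (i + 1L == params$emergence_batch) {
      tot <- wt[i + 1L] + mut[i + 1L]
      mut[i + 1L] <- params$initial_fraction * tot
      wt[i + 1L] <- (1 - params$initial_fraction) * tot
    }
  }
  list(wt = wt, mut = mut)
}

#' Apparent per-batch growth rates of a competing population
#'
#' The apparent rate of batch \eqn{i} is
#' \eqn{\ln(X_{tot,end}/X_{tot,start}) / \Delta t_i}, computed in closed form
#' from the batch-start recursion. Rates are non-decreasing once the mutant
#' is present and are bounded by `[mu_wt, mu_evo]`.
#'
#' @inheritParams competition_trajectory
#' @param t_end End time (h) of the final batch.
#'
#' @return A tibble with columns `batch`, `t_start`, `t_end`,
#'   `mutant_fraction` (at batch start) and `apparent_mu`.
#' @export
competition_apparent_rates <- function(params, transfer_times, t_end) {
  stopifnot(inherits(params, "competition_params"))
  transfer_times <- as.numeric(transfer_times)
  if (length(transfer_times) != params$n_batches - 1L) {
    stop("number of transfer times must equal n_batches - 1", call. = FALSE)
  }
  if (t_end <= max(c(0, transfer_times))) {
    stop("`t_end` must exceed the last transfer time", call. = FALSE)
  }
  st <- competition_batch_starts(params, transfer_times)
  t_open <- c(0, transfer_times)
  t_close <- c(transfer_times, t_end)
  dt <- t_close - t_open
  tot0 <- st$wt + st$mut
  tot1 <- st$wt * exp(params$mu_wt * dt) + st$mut * exp(params$mu_evo * dt)
  tibble::tibble(
    batch = seq_len(params$n_batches),
    t_start = t_open, t_end = t_close,
    mutant_fraction = st$mut / tot0,
    apparent_mu = log(tot1 / tot0) / dt
  )
}
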