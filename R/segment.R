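#' Segment a backscatter series into blank-corrected batch slices
#'
#' Splits a long-format backscatter time series into one slice per batch and
#' normalizes each against the destination well's pre-inoculation signal
#' (its blank), which removes well-specific background before any growth
#' computation. Batch boundaries come from the event log when available;
#' otherwise transfers are detected where the group's signal drops by more
#' than `detect_drop_frac` between consecutive measurement cycles (a
#' transfer dilutes the culture ~17-fold, far more than any plausible
#' measurement artefact).
#'
#' Slices with fewer than `min_points` observations are excluded with a
#' warning.
#'
#' @param ts Long tibble with columns `well`, `time_h`, `value` (raw
#'   backscatter) as produced by [gen_rbale_dataset()] or read from CSV.
#' @param events Optional event-log tibble from [run_schedule()].
#' @param detect_drop_frac Fractional drop that calls a transfer when
#'   detecting (default 0.5).
#' @param min_points Minimum observations per slice (default 4).
#'
#' @return A tibble of class `rbale_slices` with columns `group`, `batch`,
#'   `well`, `time_h`, `bs` (blank-corrected backscatter), `blank`.
#' @export
segment_and_normalize <- function(ts, events = NULL, detect_drop_frac = 0.5,
                                  min_points = 4) {
  stopifnot(is.data.frame(ts), all(c("well", "time_h", "value") %in% names(ts)))
  slices <- if (!is.null(events)) {
    segment_from_events(ts, events)
  } else {
    segment_by_detection(ts, detect_drop_frac)
  }
  n_pts <- table(slices$slice_key)
  small <- names(n_pts)[n_pts < min_points]
  if (length(small)) {
    warning(sprintf("excluded %d slice(s) with fewer than %d points",
                    length(small), min_points), call. = FALSE)
    slices <- slices[!slices$slice_key %in% small, ]
  }
  slices$slice_key <- NULL
  class(slices) <- c("rbale_slices", class(slices))
  slices
}

segment_from_events <- function(ts, events) {
  inoc <- events[events$kind == "inoculate", ]
  harv <- events[events$kind == "harvest", ]
  purrr::pmap_dfr(inoc, function(time_h, kind, source, dest, batch, group, ...) {
    t0 <- time_h
    h <- harv[harv$group == group & harv$batch == batch, ]
    t1 <- if (nrow(h)) h$time_h[1] else Inf
    w <- ts[ts$well == dest, ]
    blank_vals <- w$value[w$time_h < t0 - 1e-9]
    blank <- if (length(blank_vals)) blank_vals[length(blank_vals)] else 0
    inwin <- w$time_h >= t0 - 1e-9 & w$time_h <= t1 + 1e-9
    tibble::tibble(group = group, batch = as.integer(batch), well = dest,
                   time_h = w$time_h[inwin], bs = w$value[inwin] - blank,
                   blank = blank,
                   slice_key = paste(group, batch, sep = ":"))
  })
}

segment_by_detection <- function(ts, detect_drop_frac) {
  # group-level signal: the active culture dominates blanks at every cycle
  pooled <- dplyr::summarise(dplyr::group_by(ts, .data$time_h),
                             value = max(.data$value), .groups = "drop")
  pooled <- pooled[order(pooled$time_h), ]
  v <- pooled$value
  drop <- c(FALSE, v[-1] < (1 - detect_drop_frac) * v[-length(v)])
  cuts <- pooled$time_h[drop]
  rise <- which(v > min(v) * 2)
  first_active <- if (length(rise)) pooled$time_h[rise[1]] else pooled$time_h[1]
  starts <- c(first_active, cuts)
  ends <- c(cuts, max(pooled$time_h) + 1)
  purrr::map_dfr(seq_along(starts), function(b) {
    inwin <- ts$time_h >= starts[b] - 1e-9 & ts$time_h < ends[b] - 1e-9
    win <- ts[inwin, ]
    means <- tapply(win$value, win$well, mean)
    active <- names(means)[which.max(means)]
    w <- win[win$well == active, ]
    pre <- ts$value[ts$well == active & ts$time_h < starts[b] - 1e-9]
    blank <- if (length(pre)) pre[length(pre)] else 0
    tibble::tibble(group = "detected", batch = b, well = active,
                   time_h = w$time_h, bs = w$value - blank, blank = blank,
                   slice_key = paste("detected", b, sep = ":"))
  })
}

#' Log-linear growth-rate estimate per batch slice
#'
#' The slope of the least-squares line through (t, ln BS) over each slice's
#' blank-corrected points. Exact on noiseless exponential data and the
#' model-free oracle against which the model-based fit is checked. Slices
#' containing non-positive corrected values are rejected with a warning.
#'
#' @param slices An `rbale_slices` tibble from [segment_and_normalize()].
#'
#' @return A tibble with columns `group`, `batch`, `well`, `mu_hat` (1/h),
#'   `n_points`.
#' @examples
#' d <- gen_rbale_dataset("constant", n_batches = 3,
#'                        noise = noise_model(cv = 0), seed = 1)
#' loglinear_mu(segment_and_normalize(d$ts, d$events))
#' @export
loglinear_mu <- function(slices) {
  stopifnot(is.data.frame(slices),
            all(c("group", "batch", "well", "time_h", "bs") %in% names(slices)))
  out <- purrr::map_dfr(
    split(slices, paste(slices$group, slices$batch, sep = ":")),
    function(s) {
      if (any(s$bs <= 0)) {
        warning(sprintf("slice %s:%d rejected: non-positive corrected backscatter",
                        s$group[1], s$batch[1]), call. = FALSE)
        return(NULL)
      }
      slope <- if (nrow(s) >= 2) {
        unname(coef(stats::lm.fit(cbind(1, s$time_h), log(s$bs)))[2])
      } else NA_real_
      tibble::tibble(group = s$group[1], batch = s$batch[1], well = s$well[1],
                     mu_hat = slope, n_points = nrow(s))
    })
  if (!nrow(out)) {
    return(tibble::tibble(group = character(), batch = integer(),
                          well = character(), mu_hat = numeric(),
                          n_points = integer()))
  }
  out[order(out$group, out$batch), ]
}
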