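#' Fit the repetitive-batch growth model to a backscatter series
#'
#' Minimizes the sum of squared differences between blank-corrected
#' backscatter and the piecewise-exponential model over one growth rate per
#' batch, a single shared dilution factor, and the initial biomass, using
#' multi-start Levenberg-Marquardt least squares (`minpack.lm::nls.lm`).
#' Transfer timestamps are taken from the event log (or detected, see
#' [segment_and_normalize()]); starting values come from the log-linear
#' per-batch slopes, the nominal pipetting dilution factor (17), and the
#' first observation.
#'
#' The calibration is fixed at the identity (`a = 1`, `b = 0`) by default
#' because slope, offset and initial biomass are jointly unidentifiable from
#' backscatter alone; growth rates and the dilution factor are unaffected by
#' this choice. Supplying `calib` reports biomass on that scale instead.
#' Batches listed in `exclude_batches` (for instance a known-anomalous first
#' batch) are masked from the objective; exclusion is always explicit, never
#' automatic.
#'
#' @param ts Long backscatter tibble (`well`, `time_h`, `value`).
#' @param events Optional event log; when `NULL` transfers are detected.
#' @param exclude_batches Integer batch indices to mask from fitting.
#' @param n_starts Number of seeded multi-start runs (default 10).
#' @param seed Integer seed for start-point jitter.
#' @param calib Optional [calibration()] used to report biomass units.
#' @param max_iter Maximum optimizer iterations per start.
#'
#' @return An object of class `rbale_fit` with elements `estimates`
#'   (tibble of all parameters), `per_batch` (tibble `batch`, `mu_est`),
#'   `f_dil`, `X0`, `residuals`, `fitted`, `objective`, `converged`,
#'   `n_starts`, `seed`. Methods: [tidy()], [glance()], [autoplot()],
#'   [bootstrap_ci()].
#' @examples
#' d <- gen_rbale_dataset("constant", n_batches = 4,
#'                        noise = noise_model(cv = 0), seed = 1)
#' fit <- fit_rbale(d$ts, d$events, n_starts = 2)
#' tidy(fit)
#' @export
fit_rbale <- function(ts, events = NULL, exclude_batches = integer(0),
                      n_starts = 10, seed = 1, calib = NULL, max_iter = 500) {
  slices <- if (inherits(ts, "rbale_slices")) ts else
    segment_and_normalize(ts, events)
  slices <- slices[!slices$batch %in% exclude_batches, ]
  batches <- sort(unique(slices$batch))
  n_b <- length(batches)
  if (n_b < 1L) stop("no batches left to fit", call. = FALSE)
  # transfer timestamps = slice start times; growth of batch i runs up to the
  # start of batch i+1 (dilution is instantaneous at that timestamp)
  t_start <- vapply(split(slices$time_h, slices$batch), min, numeric(1))
  t_start <- t_start[order(as.integer(names(t_start)))]
  obs <- slices$bs
  b_idx <- match(slices$batch, batches)
  tt <- slices$time_h

  predict_bs <- function(par) {
    mu <- par[seq_len(n_b)]
    f_dil <- exp(par[n_b + 1L])
    X0 <- exp(par[n_b + 2L])
    dur <- diff(t_start)
    logstart <- log(X0) + c(0, cumsum(mu[-n_b] * dur - log(f_dil)))
    exp(logstart[b_idx] + mu[b_idx] * (tt - t_start[b_idx]))
  }
  resid_fun <- function(par, y = obs) predict_bs(par) - y

  ll <- loglinear_mu(slices)
  mu0 <- pmax(ll$mu_hat[match(batches, ll$batch)], 1e-3)
  start0 <- c(mu0, log(17), log(max(obs[which.min(tt)], 1e-6)))
  lower <- c(rep(0, n_b), log(1 + 1e-6), -Inf)

  starts <- with_local_seed(seed, purrr::map(seq_len(n_starts), function(k) {
    if (k == 1L) start0 else start0 * exp(rnorm(length(start0), sd = 0.1))
  }))
  runs <- purrr::map(starts, function(s) {
    tryCatch(minpack.lm::nls.lm(
      par = s, fn = resid_fun, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(converged = FALSE, objective = NA_real_,
                          n_starts = n_starts, seed = seed,
                          diagnostics = "no start converged"),
                     class = "rbale_fit"))
  }
  objectives <- vapply(runs, function(r) if (is.null(r)) Inf else r$deviance,
                       numeric(1))
  best <- runs[[which.min(objectives)]]
  par <- best$par
  mu_est <- par[seq_len(n_b)]
  f_dil_est <- exp(par[n_b + 1L])
  X0_est <- exp(par[n_b + 2L])
  if (!is.null(calib)) X0_est <- bs_to_biomass(X0_est + calib$b, calib)
  fitted <- predict_bs(par)

  out <- list(
    estimates = tibble::tibble(
      term = c(paste0("mu_", batches), "f_dil", "X0"),
      estimate = c(mu_est, f_dil_est, X0_est)),
    per_batch = tibble::tibble(batch = batches, mu_est = mu_est,
                               n_points = as.integer(table(b_idx))),
    f_dil = f_dil_est, X0 = X0_est,
    residuals = tibble::tibble(group = slices$group, batch = slices$batch,
                               time_h = tt, observed = obs, fitted = fitted,
                               residual = obs - fitted),
    fitted = fitted, objective = best$deviance,
    converged = best$info %in% 1:4, info = best$info,
    n_starts = n_starts, seed = seed, slices = slices,
    transfer_times = t_start,
    refit = function(y_new, start = par) {
      r <- tryCatch(minpack.lm::nls.lm(
        par = start, fn = resid_fun, y = y_new, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      list(par = c(r$par[seq_len(n_b)], exp(r$par[n_b + 1L]),
                   exp(r$par[n_b + 2L])),
           converged = r$info %in% 1:4)
    })
  class(out) <- "rbale_fit"
  out
}

#' @export
print.rbale_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.na(x$objective %||% NA)) {
    cat("<rbale_fit> not converged:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("<rbale_fit> %d batches: mu in [%.3g, %.3g] 1/h, f_dil = %.3g, X0 = %.3g (SSQ %.4g, %s)\n",
              nrow(x$per_batch), min(x$per_batch$mu_est),
              max(x$per_batch$mu_est), x$f_dil, x$X0, x$objective,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname fit_rbale
#' @param x An `rbale_fit` object.
#' @method tidy rbale_fit
#' @export
tidy.rbale_fit <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(out, x$ci, by = "term")
  }
  out
}

#' @rdname fit_rbale
#' @method glance rbale_fit
#' @export
glance.rbale_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_batches = nrow(x$per_batch %||% tibble::tibble()),
                 nobs = nrow(x$residuals %||% tibble::tibble()),
                 n_starts = x$n_starts)
}
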