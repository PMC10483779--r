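#' Residual-bootstrap confidence intervals for a fit
#'
#' Resamples residuals with replacement, perturbs the fitted values with
#' them, refits from the point estimate, and reports percentile intervals
#' of the bootstrap distribution. Because the measurement error of
#' scattered-light and offline concentration signals is predominantly
#' multiplicative, residuals are resampled on the relative scale by default
#' (`scale = "relative"`: the fitted curve is multiplied by resampled
#' relative residuals), which keeps the error structure intact across the
#' large dynamic range of a batch; `scale = "absolute"` resamples raw
#' residuals instead. Seeded and reproducible: the same seed yields
#' identical intervals. If fewer than half of the bootstrap refits converge
#' the intervals are flagged unreliable.
#'
#' @param fit An `rbale_fit` or `monod_fit` object (must have converged).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @param scale Resample residuals on the `"relative"` (default) or
#'   `"absolute"` scale.
#' @param ... Unused.
#'
#' @return The fit object with a `ci` tibble (`term`, `level`, `conf.low`,
#'   `conf.high`, `n_boot_ok`, `reliable`) merged into [tidy()] output.
#' @export
bootstrap_ci <- function(fit, n_boot = 100, level = 0.95, seed = 1,
                         scale = c("relative", "absolute"), ...) {
  UseMethod("bootstrap_ci")
}

percentile_ci <- function(draws, terms, estimates, level, n_boot) {
  alpha <- (1 - level) / 2
  ok <- nrow(draws)
  reliable <- ok >= n_boot / 2
  if (!reliable) {
    warning(sprintf("only %d/%d bootstrap refits converged; intervals unreliable",
                    ok, n_boot), call. = FALSE)
  }
  tibble::tibble(
    term = terms, level = level,
    conf.low = apply(draws, 2, quantile, probs = alpha, names = FALSE),
    conf.high = apply(draws, 2, quantile, probs = 1 - alpha, names = FALSE),
    n_boot_ok = ok, reliable = reliable)
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.rbale_fit <- function(fit, n_boot = 100, level = 0.95, seed = 1,
                                   scale = c("relative", "absolute"), ...) {
  if (!isTRUE(fit$converged)) stop("fit has not converged", call. = FALSE)
  scale <- match.arg(scale)
  fitted <- fit$fitted
  res <- if (scale == "relative") {
    fit$residuals$residual / pmax(abs(fitted), 0.05 * max(abs(fitted)))
  } else {
    fit$residuals$residual
  }
  draws <- with_local_seed(seed, {
    reps <- purrr::map(seq_len(n_boot), function(i) {
      e <- sample(res, length(res), replace = TRUE)
      y_star <- if (scale == "relative") fitted * (1 + e) else fitted + e
      r <- fit$refit(y_star)
      if (is.null(r) || !r$converged) NULL else r$par
    })
    do.call(rbind, purrr::compact(reps))
  })
  fit$ci <- percentile_ci(draws, fit$estimates$term, fit$estimates$estimate,
                          level, n_boot)
  fit
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.monod_fit <- function(fit, n_boot = 100, level = 0.95, seed = 1,
                                   scale = c("relative", "absolute"), ...) {
  if (!isTRUE(fit$converged)) stop("fit has not converged", call. = FALSE)
  scale <- match.arg(scale)
  res <- fit$residuals
  n_r <- length(fit$reactors)
  fitted_X <- purrr::map(seq_len(n_r), function(r) {
    res$fitted[res$reactor == fit$reactors[r] & res$observable == "cdw_gL"]
  })
  fitted_S <- purrr::map(seq_len(n_r), function(r) {
    res$fitted[res$reactor == fit$reactors[r] & res$observable == "substrate_gL"]
  })
  sel_X <- res$observable == "cdw_gL"
  sel_S <- res$observable == "substrate_gL"
  if (scale == "relative") {
    fx <- res$fitted[sel_X]; fs <- res$fitted[sel_S]
    rX <- res$residual[sel_X] / pmax(abs(fx), 0.05 * max(abs(fx)))
    rS <- res$residual[sel_S] / pmax(abs(fs), 0.05 * max(abs(fs)))
    perturb <- function(f, r) f * (1 + sample(r, length(f), replace = TRUE))
  } else {
    rX <- res$residual[sel_X]
    rS <- res$residual[sel_S]
    perturb <- function(f, r) f + sample(r, length(f), replace = TRUE)
  }
  draws <- with_local_seed(seed, {
    reps <- purrr::map(seq_len(n_boot), function(i) {
      yX <- purrr::map(fitted_X, perturb, r = rX)
      yS <- purrr::map(fitted_S, perturb, r = rS)
      r <- fit$refit(yX, yS)
      if (is.null(r) || !r$converged) NULL else r$par
    })
    do.call(rbind, purrr::compact(reps))
  })
  fit$ci <- percentile_ci(draws, fit$estimates$term, fit$estimates$estimate,
                          level, n_boot)
  fit
}
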