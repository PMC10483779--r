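#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: raw backscatter per
#' well for datasets, observed-versus-fitted curves for fits, well
#' occupancy for schedules, and `plot_batch_rates()` shows estimated
#' per-batch growth rates (with bootstrap intervals when present).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rbale-plots
NULL

#' @rdname rbale-plots
#' @method autoplot rbale_dataset
#' @export
autoplot.rbale_dataset <- function(object, ...) {
  ggplot2::ggplot(object$ts,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               colour = .data$well)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "time (h)", y = "backscatter (a.u.)",
                  title = sprintf("rbALE dataset (%s scenario)",
                                  object$truth$scenario)) +
    ggplot2::theme_minimal()
}

#' @rdname rbale-plots
#' @method autoplot rbale_fit
#' @export
autoplot.rbale_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.5,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, group = .data$batch),
                       colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "blank-corrected backscatter (a.u.)",
                  title = "rbALE model fit") +
    ggplot2::theme_minimal()
}

#' @rdname rbale-plots
#' @method autoplot monod_fit
#' @export
autoplot.monod_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, colour = .data$observable)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(~reactor) +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)",
                  title = "Hierarchical Monod fit") +
    ggplot2::theme_minimal()
}

#' @rdname rbale-plots
#' @method autoplot rbale_schedule
#' @export
autoplot.rbale_schedule <- function(object, ...) {
  b <- object$batches
  ggplot2::ggplot(b, ggplot2::aes(y = .data$well)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                                       yend = .data$well,
                                       colour = .data$group),
                          linewidth = 3) +
    ggplot2::labs(x = "time (h)", y = NULL, title = "Well occupancy") +
    ggplot2::theme_minimal()
}

#' @rdname rbale-plots
#' @param fit An `rbale_fit` object.
#' @export
plot_batch_rates <- function(fit, ...) {
  stopifnot(inherits(fit, "rbale_fit"))
  d <- fit$per_batch
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$batch, y = .data$mu_est))
  if (!is.null(fit$ci)) {
    ci <- fit$ci[grepl("^mu_", fit$ci$term), ]
    ci$batch <- as.integer(sub("^mu_", "", ci$term))
    d2 <- dplyr::left_join(d, ci[, c("batch", "conf.low", "conf.high")],
                           by = "batch")
    p <- ggplot2::ggplot(d2, ggplot2::aes(x = .data$batch, y = .data$mu_est)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             width = 0.2)
  }
  p + ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "batch", y = expression(hat(mu) ~ (h^-1)),
                  title = "Estimated per-batch growth rates") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
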