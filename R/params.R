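#' Parameters of the repetitive-batch growth model
#'
#' The rbALE process model describes biomass `X` growing exponentially at a
#' substrate-independent specific rate within each batch; at every transfer
#' event the biomass is instantaneously diluted by a factor `f_dil`
#' (approximately 17 for a 50 uL inoculum into 800 uL fresh medium). Each
#' batch may carry its own growth rate `mu_i`, which is how evolving
#' populations (rising rates) are represented.
#'
#' @param mu Numeric vector of per-batch specific growth rates (1/h), all
#'   >= 0; its length fixes the number of batches.
#' @param f_dil Dilution factor at each transfer (> 1).
#' @param X0 Initial biomass (g CDW / L, or backscatter units under the
#'   identity calibration), > 0.
#' @param calib A [calibration()] object.
#'
#' @return An object of class `rbale_params`.
#' @examples
#' rbale_params(mu = rep(0.41, 16), f_dil = 17, X0 = 8)
#' @export
rbale_params <- function(mu, f_dil = 17, X0 = 8, calib = calibration()) {
  stopifnot(is.numeric(mu), length(mu) >= 1L, all(is.finite(mu)),
            is.numeric(f_dil), length(f_dil) == 1L, is.finite(f_dil),
            is.numeric(X0), length(X0) == 1L, is.finite(X0),
            inherits(calib, "rbale_calibration"))
  if (any(mu < 0)) stop("growth rates `mu` must be >= 0", call. = FALSE)
  if (f_dil <= 1) stop("dilution factor `f_dil` must be > 1", call. = FALSE)
  if (X0 <= 0) stop("initial biomass `X0` must be > 0", call. = FALSE)
  structure(list(mu = as.numeric(mu), f_dil = f_dil, X0 = X0, calib = calib),
            class = "rbale_params")
}

#' @export
print.rbale_params <- function(x, ...) {
  cat(sprintf("<rbale_params> %d batches, mu in [%.3g, %.3g] 1/h, f_dil = %.3g, X0 = %.3g\n",
              length(x$mu), min(x$mu), max(x$mu), x$f_dil, x$X0))
  invisible(x)
}

#' Parameters of the wild-type / mutant competition model
#'
#' Two subpopulations grow exponentially at rates `mu_wt` and `mu_evo`
#' (`mu_evo > mu_wt`) and share every transfer event (both are diluted by
#' `f_dil`). The mutant appears at the start of `emergence_batch` as a
#' fraction `initial_fraction` of the total biomass, emulating a single-cell
#' beneficial mutation whose takeover produces the apparent batch-to-batch
#' rise of the population growth rate.
#'
#' @param mu_wt,mu_evo Wild-type and mutant specific growth rates (1/h),
#'   `mu_evo > mu_wt >= 0`.
#' @param emergence_batch Batch index (1-based) at whose start the mutant
#'   appears.
#' @param initial_fraction Mutant biomass fraction at emergence, in (0, 1).
#' @param n_batches Number of batches simulated.
#' @inheritParams rbale_params
#'
#' @return An object of class `competition_params`.
#' @export
competition_params <- function(mu_wt, mu_evo, emergence_batch = 1L,
                               initial_fraction = 1e-6, n_batches = 16L,
                               f_dil = 17, X0 = 8, calib = calibration()) {
  stopifnot(is.numeric(mu_wt), is.numeric(mu_evo),
            length(mu_wt) == 1L, length(mu_evo) == 1L)
  if (!(mu_evo > mu_wt && mu_wt >= 0)) {
    stop("require mu_evo > mu_wt >= 0", call. = FALSE)
  }
  if (!(initial_fraction > 0 && initial_fraction < 1)) {
    stop("`initial_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_batches <- as.integer(n_batches)
  emergence_batch <- as.integer(emergence_batch)
  if (emergence_batch < 1L || emergence_batch > n_batches) {
    stop("`emergence_batch` must lie within the run", call. = FALSE)
  }
  base <- rbale_params(mu = rep(mu_wt, n_batches), f_dil = f_dil, X0 = X0,
                       calib = calib)
  structure(c(base[c("f_dil", "X0", "calib")],
              list(mu_wt = mu_wt, mu_evo = mu_evo,
                   emergence_batch = emergence_batch,
                   initial_fraction = initial_fraction,
                   n_batches = n_batches)),
            class = "competition_params")
}

#' @export
print.competition_params <- function(x, ...) {
  cat(sprintf(
    "<competition_params> mu_wt = %.3g, mu_evo = %.3g 1/h, mutant from batch %d (fraction %.2g), %d batches\n",
    x$mu_wt, x$mu_evo, x$emergence_batch, x$initial_fraction, x$n_batches))
  invisible(x)
}

#' Parameters of the Monod batch model
#'
#' Classical Monod kinetics for a batch culture:
#' \deqn{dX/dt = \mu_{max} S/(K_S + S) \, X, \qquad
#'       dS/dt = -\frac{1}{Y_{X/S}} \mu_{max} S/(K_S + S)\, X.}
#' The kinetic parameters (`mu_max`, `K_S`, `Y_XS`) are global, shared by all
#' replicate reactors; the initial conditions (`X0`, `S0`) are local, one
#' record per reactor, because each reactor is inoculated separately.
#'
#' @param mu_max Maximum specific growth rate (1/h), > 0.
#' @param K_S Monod affinity constant (g/L), > 0.
#' @param Y_XS Biomass yield (g CDW per g substrate), in (0, 1).
#' @param locals Data frame with one row per replicate and columns `X0`
#'   (g CDW / L) and `S0` (g/L).
#'
#' @return An object of class `monod_params`.
#' @examples
#' monod_params(mu_max = 0.15, K_S = 0.01, Y_XS = 0.45,
#'              locals = data.frame(X0 = 0.875, S0 = mM_to_gL(428)))
#' @export
monod_params <- function(mu_max, K_S, Y_XS, locals) {
  stopifnot(is.numeric(mu_max), mu_max > 0,
            is.numeric(K_S), K_S > 0,
            is.numeric(Y_XS))
  if (!(Y_XS > 0 && Y_XS < 1)) stop("`Y_XS` must lie in (0, 1)", call. = FALSE)
  locals <- tibble::as_tibble(locals)
  if (!all(c("X0", "S0") %in% names(locals)) || nrow(locals) < 1L) {
    stop("`locals` needs columns X0, S0 and at least one row", call. = FALSE)
  }
  if (any(locals$X0 <= 0) || any(locals$S0 <= 0)) {
    stop("local initial conditions must be positive", call. = FALSE)
  }
  structure(list(mu_max = mu_max, K_S = K_S, Y_XS = Y_XS, locals = locals),
            class = "monod_params")
}

#' @export
print.monod_params <- function(x, ...) {
  cat(sprintf("<monod_params> mu_max = %.3g 1/h, K_S = %.3g g/L, Y_XS = %.3g g/g, %d replicate(s)\n",
              x$mu_max, x$K_S, x$Y_XS, nrow(x$locals)))
  invisible(x)
}
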