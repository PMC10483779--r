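#' Linear backscatter calibration
#'
#' A linear model mapping backscatter (BS, arbitrary units) to biomass
#' concentration \eqn{X} (g CDW / L): \eqn{X = (BS - b) / a}. The slope `a`
#' has units of backscatter per g/L and the offset `b` is in backscatter
#' units. The identity calibration (`a = 1`, `b = 0`) reports biomass in
#' backscatter units, which is the estimation default because `a`, `b` and
#' the initial biomass are jointly degenerate given backscatter alone.
#'
#' @param a Slope (backscatter units per g CDW / L), must be > 0.
#' @param b Offset (backscatter units), must be >= 0.
#'
#' @return An object of class `rbale_calibration`.
#' @examples
#' cal <- calibration(a = 2, b = 10)
#' bs_to_biomass(20, cal)  # 5
#' @export
calibration <- function(a = 1, b = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a <= 0) stop("calibration slope `a` must be > 0", call. = FALSE)
  if (b < 0) stop("calibration offset `b` must be >= 0", call. = FALSE)
  structure(list(a = a, b = b), class = "rbale_calibration")
}

#' @export
print.rbale_calibration <- function(x, ...) {
  cat(sprintf("<calibration> X = (BS - %g) / %g\n", x$b, x$a))
  invisible(x)
}

#' Convert backscatter to biomass and back
#'
#' `bs_to_biomass()` applies the forward calibration \eqn{X = (BS - b)/a};
#' `biomass_to_bs()` applies the inverse \eqn{BS = aX + b}. The round trip is
#' the identity to machine precision.
#'
#' @param bs,x Numeric vectors of backscatter / biomass values.
#' @param calib A [calibration()] object.
#'
#' @return Numeric vector of the same length.
#' @export
bs_to_biomass <- function(bs, calib = calibration()) {
  stopifnot(inherits(calib, "rbale_calibration"), is.numeric(bs), all(is.finite(bs)))
  if (any(bs < calib$b)) {
    stop("negative biomass: backscatter below calibration offset `b`", call. = FALSE)
  }
  (bs - calib$b) / calib$a
}

#' @rdname bs_to_biomass
#' @export
biomass_to_bs <- function(x, calib = calibration()) {
  stopifnot(inherits(calib, "rbale_calibration"), is.numeric(x), all(is.finite(x)))
  calib$a * x + calib$b
}

#' Generations between two backscatter readings
#'
#' Number of doublings implied by the blank-corrected backscatter increase
#' over a batch, \eqn{\log_2(BS_{end}/BS_{start})}. With the default workflow
#' (start BS around 8, trigger threshold 60) each batch spans about three
#' generations, independent of growth rate and organism.
#'
#' @param bs_start,bs_end Positive blank-corrected backscatter values;
#'   vectors are recycled pairwise.
#'
#' @return Generations (numeric).
#' @examples
#' generations_between(8, 60)   # ~2.91, i.e. about three generations
#' generations_between(8, 16)   # exactly one doubling
#' @export
generations_between <- function(bs_start, bs_end) {
  stopifnot(is.numeric(bs_start), is.numeric(bs_end))
  if (any(!is.finite(bs_start)) || any(!is.finite(bs_end)) ||
      any(bs_start <= 0) || any(bs_end <= 0)) {
    stop("backscatter values must be finite and positive", call. = FALSE)
  }
  log2(bs_end / bs_start)
}

#' Molar masses used for mM <-> g/L substrate conversion
#' @format Named numeric vector (g/mol) with entries `ethanol` and `glucose`.
#' @export
molar_masses <- c(ethanol = 46.069, glucose = 180.156)

#' Convert substrate concentrations between mM and g/L
#'
#' @param x Concentration values.
#' @param molar_mass Substrate molar mass in g/mol (see [molar_masses]).
#' @return Converted concentrations.
#' @export
mM_to_gL <- function(x, molar_mass = molar_masses[["ethanol"]]) {
  x * molar_mass / 1000
}

#' @rdname mM_to_gL
#' @export
gL_to_mM <- function(x, molar_mass = molar_masses[["ethanol"]]) {
  x * 1000 / molar_mass
}
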