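#' Light transmittance inversion model
#'
#' The Warren-Wilson turbid-medium model relates the gap fraction P0 at
#' view zenith angle theta to LAI through
#' `P0 = exp(-k * LAI)` with extinction coefficient
#' `k = G(theta) / cos(theta)`, where G is the leaf projection function.
#' At theta = 57.5 degrees, G is close to 0.5 regardless of the leaf angle
#' distribution, which is why the acquisition protocol fixes that angle:
#' the inversion needs no canopy-specific calibration.
#'
#' @param theta_deg view zenith angle in degrees. Default 57.5.
#' @param g_value leaf projection function G(theta). Default 0.5, the
#'   theoretical value at 57.5 degrees; exposed for sensitivity analyses.
#' @return An object of class `inversion_model` with fields `theta_deg`,
#'   `g_value` and the derived extinction coefficient `k`
#'   (0.9306 with the defaults).
#' @export
inversion_model <- function(theta_deg = 57.5, g_value = 0.5) {
  if (theta_deg <= 0 || theta_deg >= 90)
    vinelai_config_error("'theta_deg' must lie in (0, 90)")
  if (g_value <= 0)
    vinelai_config_error("'g_value' must be positive")
  k <- g_value / cos(theta_deg * pi / 180)
  structure(list(theta_deg = theta_deg, g_value = g_value, k = k),
            class = "inversion_model")
}

#' @export
print.inversion_model <- function(x, ...) {
  cat(sprintf("<inversion_model> theta = %.1f deg, G = %.3f, k = %.6f\n",
              x$theta_deg, x$g_value, x$k))
  invisible(x)
}

#' Invert gap fraction to plant LAI
#'
#' `LAI = -ln(P0) / k`. Strictly decreasing in P0, with LAI(1) = 0.
#' P0 = 0 is outside the domain (a fully closed frame): clamp it first with
#' [clamp_saturated()].
#'
#' @param p0 gap fraction(s) in `(0, 1]`; vectorised.
#' @param model an [inversion_model()].
#' @return Plant LAI estimate(s) on the instrument reference area
#'   (dimensionless).
#' @export
lai_from_gap_fraction <- function(p0, model = inversion_model()) {
  if (!inherits(model, "inversion_model"))
    vinelai_input_error("'model' must be an inversion_model")
  if (any(!is.finite(p0)) || any(p0 <= 0) || any(p0 > 1))
    vinelai_input_error(
      "gap fraction must lie in (0, 1]; P0 = 0 means a saturated frame - clamp it with clamp_saturated() first")
  -log(p0) / model$k
}

#' Clamp a saturated gap fraction to the half-pixel resolution floor
#'
#' A frame without detected sky pixels yields P0 = 0, which the logarithmic
#' inversion cannot handle; physically the instrument has only established
#' P0 < 1/n_total. Gap fractions below half a pixel's worth,
#' `1 / (2 * n_total)`, are raised to that floor and flagged, so dense
#' canopies produce a finite (under-)estimate instead of an error - the
#' saturation behaviour expected of transmittance-based methods.
#'
#' @param p0 observed gap fraction(s).
#' @param n_total number of pixels in the frame.
#' @return A list with `p0` (clamped values) and `saturated` (logical,
#'   `TRUE` where the floor was applied); both vectorised over `p0`.
#' @export
clamp_saturated <- function(p0, n_total) {
  if (length(n_total) != 1L || n_total <= 0)
    vinelai_input_error("'n_total' must be a single positive count")
  floor_p0 <- 1 / (2 * n_total)
  sat <- p0 < floor_p0
  list(p0 = ifelse(sat, floor_p0, p0), saturated = sat)
}
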