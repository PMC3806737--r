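#' Plane-wave acoustic intensity from peak pressure
#'
#' For a travelling plane wave the time-averaged intensity is
#' `I = p^2 / (2 rho0 c)` with `p` the peak acoustic pressure — the
#' relation used to calibrate unfocused-transducer intensities from
#' hydrophone measurements.
#'
#' @param p Peak acoustic pressure (Pa), non-negative.
#' @param med A [medium_properties()].
#' @return Intensity (W/m^2). Divide by 1e4 for W/cm^2.
#' @examples
#' intensity_from_pressure(135e3, medium_properties()) / 1e4  # ~0.61 W/cm^2
#' @export
intensity_from_pressure <- function(p, med = medium_properties()) {
  stopifnot(inherits(med, "medium_properties"))
  if (any(p < 0)) stop("peak pressure must be non-negative")
  p^2 / (2 * med$rho * med$c)
}

#' Peak pressure from plane-wave intensity (inverse of
#' [intensity_from_pressure()])
#'
#' @param I Intensity (W/m^2), non-negative.
#' @param med A [medium_properties()].
#' @return Peak acoustic pressure (Pa).
#' @export
pressure_from_intensity <- function(I, med = medium_properties()) {
  stopifnot(inherits(med, "medium_properties"))
  if (any(I < 0)) stop("intensity must be non-negative")
  sqrt(2 * med$rho * med$c * I)
}

#' Intensity from the peak velocity of a reflecting air/water interface
#'
#' At a pressure-release (air/water) interface the incident wave is totally
#' reflected and the interface moves with twice the incident particle
#' velocity, so the incident intensity in terms of the peak interface
#' velocity `u` is `I = rho0 c u^2 / 8` — the relation used to calibrate
#' focused-transducer intensities from vibrometer measurements.
#'
#' @param u_iface Peak interface velocity (m/s), non-negative.
#' @param med A [medium_properties()].
#' @return Intensity (W/m^2).
#' @export
intensity_from_interface_velocity <- function(u_iface,
                                              med = medium_properties()) {
  stopifnot(inherits(med, "medium_properties"))
  if (any(u_iface < 0)) stop("interface velocity must be non-negative")
  med$rho * med$c * u_iface^2 / 8
}

#' Peak interface velocity from intensity (inverse of
#' [intensity_from_interface_velocity()])
#'
#' @param I Intensity (W/m^2), non-negative.
#' @param med A [medium_properties()].
#' @return Peak interface velocity (m/s).
#' @export
interface_velocity_from_intensity <- function(I,
                                              med = medium_properties()) {
  stopifnot(inherits(med, "medium_properties"))
  if (any(I < 0)) stop("intensity must be non-negative")
  sqrt(8 * I / (med$rho * med$c))
}

#' Maximal radiation pressure an ultrasound beam can exert
#'
#' A perfectly reflecting target intercepting a beam of intensity `I`
#' experiences at most `2 I / c` of radiation pressure.
#'
#' @param I Intensity (W/m^2), non-negative.
#' @param c Speed of sound (m/s), positive. Default 1500 (water).
#' @return Pressure bound (N/m^2).
#' @examples
#' max_radiation_pressure(6100)  # 610 mW/cm^2 -> ~8.1 N/m^2
#' @export
max_radiation_pressure <- function(I, c = 1500) {
  if (any(I < 0)) stop("intensity must be non-negative")
  if (c <= 0) stop("speed of sound must be positive")
  2 * I / c
}

#' Check a radiation-force pressure against the 2I/c bound
#'
#' @param P_US Radiation-force pressure (N/m^2).
#' @param I Beam intensity (W/m^2).
#' @param c Speed of sound (m/s).
#' @return Invisibly, the bound (N/m^2). Warns if `P_US` exceeds it.
#' @export
check_radiation_bound <- function(P_US, I, c = 1500) {
  bound <- max_radiation_pressure(I, c)
  if (any(P_US > bound))
    warning(sprintf(paste0("P_US = %.3g N/m^2 exceeds the maximal radiation",
                           " pressure 2I/c = %.3g N/m^2"),
                    max(P_US), bound))
  invisible(bound)
}
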