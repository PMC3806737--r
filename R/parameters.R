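#' Bilayer geometric and dielectric parameters
#'
#' Container for the membrane-side constants of the interfacial-wave model:
#' the bilayer diameter, interfacial tension, resting hydrophobic thickness
#' and the dielectric constant of the hydrophobic core. The resting surface
#' area `A0` is a derived quantity (set by [solve_equilibrium()] or
#' [resting_area()]), not a user input.
#'
#' @param d Bilayer diameter (m). Must be positive.
#' @param gamma Interfacial tension (N/m). Must be positive. Decane-formed
#'   phospholipid bilayers fall in roughly 0.4--6.5 mN/m; 0.8 mN/m is a
#'   representative value.
#' @param L0 Resting hydrophobic thickness (m). Default 4 nm, typical of
#'   solvent-containing bilayers.
#' @param epsilon Relative dielectric constant of the hydrophobic core
#'   (dimensionless, >= 1). Default 2.
#' @param A0 Optional resting (equilibrium) surface area (m^2). When set it
#'   must be at least the flat-disc area `pi * d^2 / 4`.
#' @return An object of class `bilayer_parameters`.
#' @seealso [medium_properties()], [pressure_program()], [solve_equilibrium()]
#' @examples
#' bp <- bilayer_parameters(d = 120e-6, gamma = 0.8e-3)
#' bp
#' @export
bilayer_parameters <- function(d, gamma, L0 = 4e-9, epsilon = 2, A0 = NULL) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(L0), length(L0) == 1L, is.finite(L0),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (d <= 0) stop("bilayer diameter 'd' must be positive")
  if (gamma <= 0) stop("interfacial tension 'gamma' must be positive")
  if (L0 <= 0) stop("resting thickness 'L0' must be positive")
  if (epsilon < 1) stop("relative dielectric constant 'epsilon' must be >= 1")
  bp <- structure(
    list(d = d, gamma = gamma, L0 = L0, epsilon = epsilon,
         eps0 = 8.8541878128e-12, A0 = NULL),
    class = "bilayer_parameters")
  if (!is.null(A0)) bp <- set_resting_area(bp, A0)
  bp
}

#' Set the resting surface area of a bilayer
#'
#' @param bp A [bilayer_parameters()] object.
#' @param A0 Resting surface area (m^2); must be at least the flat-disc area.
#' @return `bp` with `A0` filled in.
#' @export
set_resting_area <- function(bp, A0) {
  stopifnot(inherits(bp, "bilayer_parameters"),
            is.numeric(A0), length(A0) == 1L, is.finite(A0))
  disc <- pi * bp$d^2 / 4
  # tiny quadrature slack below the exact disc area is tolerated
  if (A0 < disc * (1 - 1e-9))
    stop("A0 must be at least the flat-disc area pi*d^2/4")
  bp$A0 <- A0
  bp
}

#' @export
print.bilayer_parameters <- function(x, ...) {
  cat("Bilayer parameters\n")
  cat(sprintf("  diameter d        : %g um\n", x$d * 1e6))
  cat(sprintf("  tension gamma     : %g mN/m\n", x$gamma * 1e3))
  cat(sprintf("  thickness L0      : %g nm\n", x$L0 * 1e9))
  cat(sprintf("  dielectric epsilon: %g\n", x$epsilon))
  if (!is.null(x$A0))
    cat(sprintf("  resting area A0   : %.4g m^2 (flat disc %.4g m^2)\n",
                x$A0, pi * x$d^2 / 4))
  invisible(x)
}

#' Physical properties of the surrounding solution
#'
#' @param rho Solution density (kg/m^3). Default 1000 (water, room
#'   temperature).
#' @param eta Dynamic viscosity (Pa s). Default 1e-3 (water).
#' @param c Speed of sound (m/s). Default 1500 (water).
#' @return An object of class `medium_properties`.
#' @examples
#' medium_properties()
#' @export
medium_properties <- function(rho = 1000, eta = 1e-3, c = 1500) {
  stopifnot(is.numeric(rho), is.numeric(eta), is.numeric(c),
            length(rho) == 1L, length(eta) == 1L, length(c) == 1L)
  if (!all(is.finite(c(rho, eta, c))) || any(c(rho, eta, c) <= 0))
    stop("medium properties rho, eta and c must all be strictly positive")
  structure(list(rho = rho, eta = eta, c = c), class = "medium_properties")
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium properties\n")
  cat(sprintf("  density rho : %g kg/m^3\n", x$rho))
  cat(sprintf("  viscosity   : %g mPa.s\n", x$eta * 1e3))
  cat(sprintf("  sound speed : %g m/s\n", x$c))
  invisible(x)
}

#' Pressure drive acting on the bilayer
#'
#' Describes the trans-bilayer pressure as a function of time: a constant
#' hydrostatic component `P0` plus a radiation-force component `P_US` gated
#' between `t_on` and `t_off`, optionally scaled by a dimensionless envelope
#' (for modulated-intensity stimuli). The total pressure is
#' `P(t) = P0 + P_US * envelope(t - t_on)` for `t_on <= t < t_off`, and `P0`
#' otherwise.
#'
#' @param P0 Hydrostatic pressure (N/m^2). Negative under the standard
#'   recording geometry (bilayer curved against the propagation direction).
#' @param P_US Radiation-force pressure amplitude (N/m^2).
#' @param t_on,t_off Stimulus onset and offset times (s); `t_off > t_on`.
#'   `t_off = Inf` gives a pure On protocol.
#' @param envelope Optional function of time-since-onset (s) returning a
#'   dimensionless intensity fraction in \[0, 1\]. `NULL` means an ideal step.
#' @return An object of class `pressure_program`.
#' @examples
#' prog <- pressure_program(P0 = -70, P_US = 0.15, t_on = 0, t_off = 10e-3)
#' total_pressure(prog, c(-1e-3, 5e-3, 20e-3))
#' @export
pressure_program <- function(P0, P_US, t_on = 0, t_off = Inf,
                             envelope = NULL) {
  stopifnot(is.numeric(P0), length(P0) == 1L, is.finite(P0),
            is.numeric(P_US), length(P_US) == 1L, is.finite(P_US),
            is.numeric(t_on), length(t_on) == 1L, is.finite(t_on),
            is.numeric(t_off), length(t_off) == 1L)
  if (!(t_off > t_on)) stop("'t_off' must be greater than 't_on'")
  if (!is.null(envelope) && !is.function(envelope))
    stop("'envelope' must be NULL or a function of time since onset")
  structure(list(P0 = P0, P_US = P_US, t_on = t_on, t_off = t_off,
                 envelope = envelope),
            class = "pressure_program")
}

#' Evaluate the total pressure of a pressure program
#'
#' @param prog A [pressure_program()].
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector `P0 + P_US * envelope` gated to the stimulus window.
#' @export
total_pressure <- function(prog, t) {
  stopifnot(inherits(prog, "pressure_program"), is.numeric(t))
  gate <- as.numeric(t >= prog$t_on & t < prog$t_off)
  env <- if (is.null(prog$envelope)) gate else {
    e <- ifelse(gate > 0, prog$envelope(t - prog$t_on), 0)
    e
  }
  prog$P0 + prog$P_US * env
}

#' @export
print.pressure_program <- function(x, ...) {
  cat("Pressure program\n")
  cat(sprintf("  hydrostatic P0 : %g N/m^2\n", x$P0))
  cat(sprintf("  radiation P_US : %g N/m^2\n", x$P_US))
  cat(sprintf("  window         : [%g, %g] ms\n",
              x$t_on * 1e3, x$t_off * 1e3))
  cat(sprintf("  envelope       : %s\n",
              if (is.null(x$envelope)) "ideal step" else "custom"))
  invisible(x)
}

#' Numerical settings for the method-of-lines solver
#'
#' @param n_nodes Number of uniformly spaced spatial grid points along the
#'   bilayer chord, rim to rim. Must be odd (so that the centre x = 0 is a
#'   node) and at least 51. Default 201.
#' @param rtol,atol Relative and absolute integrator tolerances. Defaults
#'   1e-8 and 1e-14.
#' @param dt_out Output sampling interval (s). Default 1e-5 (100 kHz, the
#'   sampling rate of the emulated recordings).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(n_nodes = 201L, rtol = 1e-8, atol = 1e-14,
                            dt_out = 1e-5) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, is.finite(n_nodes))
  if (n_nodes < 51L || n_nodes %% 2L == 0L)
    stop("'n_nodes' must be odd and >= 51 so that x = 0 is a grid node")
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0)
    stop("integrator tolerances must be positive")
  if (!is.numeric(dt_out) || dt_out <= 0) stop("'dt_out' must be positive")
  structure(list(n_nodes = n_nodes, rtol = rtol, atol = atol,
                 dt_out = dt_out),
            class = "solver_settings")
}
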