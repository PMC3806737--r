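#' Surface area of the bilayer from a displacement profile
#'
#' The cross-sectional profile `u(x)` on the half-chord `x` in `[0, d/2]` is
#' treated as the radial profile of an axisymmetric surface; the area is the
#' surface-of-revolution integral
#' \deqn{A = \int_0^{d/2} 2 \pi r \sqrt{1 + (\partial u/\partial r)^2}\, dr}
#' evaluated by adaptive quadrature on a spline interpolant of the profile.
#' A flat profile gives exactly the disc area `pi d^2 / 4`.
#'
#' @param field A `displacement_field` (from [solve_equilibrium()] or
#'   [solve_dynamics()]).
#' @param t_index Index into `field$t` selecting the time slice (default 1).
#' @return Surface area (m^2).
#' @examples
#' bp <- bilayer_parameters(120e-6, 0.8e-3)
#' eq <- solve_equilibrium(bp, P0 = 0)
#' compute_area(eq$field)          # flat disc, pi d^2 / 4
#' @export
compute_area <- function(field, t_index = 1L) {
  stopifnot(inherits(field, "displacement_field"))
  t_index <- as.integer(t_index)
  if (t_index < 1L || t_index > nrow(field$u))
    stop("'t_index' outside the stored time range")
  prof <- field$u[t_index, ]
  if (!all(is.finite(prof))) stop("non-finite displacement profile")
  right <- field$x >= 0
  r <- field$x[right]
  ur <- prof[right]
  profile_revolution_area(r, ur)
}

# area of the surface of revolution generated by radial profile u(r)
profile_revolution_area <- function(r, u) {
  if (max(abs(u)) == 0) return(pi * max(r)^2)
  sf <- stats::splinefun(r, u, method = "fmm")
  f <- function(rr) 2 * pi * rr * sqrt(1 + sf(rr, deriv = 1L)^2)
  stats::integrate(f, 0, max(r), rel.tol = 1e-9, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Hydrophobic thickness under constant-volume elastic deformation
#'
#' Elastic area changes of a bilayer conserve the hydrophobic volume, so the
#' thickness changes reciprocally with area: `L = L0 * A0 / A`.
#'
#' @param A Bilayer area(s) (m^2), positive.
#' @param bp A [bilayer_parameters()] with `A0` set.
#' @return Thickness (m), same length as `A`.
#' @export
compute_thickness <- function(A, bp) {
  stopifnot(inherits(bp, "bilayer_parameters"))
  if (is.null(bp$A0)) stop("bp$A0 is not set; run solve_equilibrium() first")
  if (!all(is.finite(A)) || any(A <= 0)) stop("areas must be positive")
  bp$L0 * bp$A0 / A
}

#' Parallel-plate capacitance of the bilayer
#'
#' `C = epsilon * eps0 * A / L` with the hydrophobic core as dielectric.
#'
#' @param A Area(s) (m^2), positive.
#' @param L Thickness(es) (m), positive.
#' @param bp A [bilayer_parameters()] (supplies `epsilon` and `eps0`).
#' @return Capacitance (F).
#' @export
compute_capacitance <- function(A, L, bp) {
  stopifnot(inherits(bp, "bilayer_parameters"))
  if (!all(is.finite(A)) || any(A <= 0)) stop("areas must be positive")
  if (!all(is.finite(L)) || any(L <= 0)) stop("thicknesses must be positive")
  bp$epsilon * bp$eps0 * A / L
}

#' Voltage-clamp / current-clamp recording configuration
#'
#' @param V0 Holding potential (V).
#' @param C0 Baseline capacitance (F), positive. May be `NULL` when it is
#'   derived from the model (`electrical_series()` fills it in).
#' @param mode `"vclamp"` (voltage clamp) or `"cclamp"` (current clamp,
#'   i.e. constant charge).
#' @return Object of class `voltage_clamp_config`.
#' @export
voltage_clamp_config <- function(V0, C0 = NULL, mode = c("vclamp", "cclamp")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(V0), length(V0) == 1L, is.finite(V0))
  if (!is.null(C0)) {
    stopifnot(is.numeric(C0), length(C0) == 1L, is.finite(C0))
    if (C0 <= 0) stop("baseline capacitance 'C0' must be positive")
  }
  structure(list(V0 = V0, C0 = C0, mode = mode),
            class = "voltage_clamp_config")
}

#' Electrical time series from a displacement field
#'
#' Full electromechanical pipeline: area by the surface-of-revolution
#' integral at each stored time, reciprocal (constant-volume) thickness,
#' parallel-plate capacitance and, in voltage-clamp mode, the capacitive
#' current `I_C = V dC/dt` (centred differences, one-sided at the ends). In
#' current-clamp mode the constant-charge voltage is attached instead (see
#' [current_clamp_voltage()]).
#'
#' @param field A `displacement_field` with at least 3 time samples.
#' @param bp A [bilayer_parameters()]; if `A0` is unset, the first stored
#'   time slice (the pre-stimulus equilibrium) defines it.
#' @param cfg A [voltage_clamp_config()].
#' @return A data frame with columns `t, A, L, C` plus `I_C` and `V`
#'   (vclamp) or `V_exact` and `V_approx` (cclamp); the resting values
#'   `A0`, `L0`, `C0` are attached as attributes.
#' @export
electrical_series <- function(field, bp, cfg) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(bp, "bilayer_parameters"),
            inherits(cfg, "voltage_clamp_config"))
  nt <- length(field$t)
  A <- vapply(seq_len(nt), function(i) compute_area(field, i), numeric(1))
  if (is.null(bp$A0)) bp <- set_resting_area(bp, A[1])
  L <- compute_thickness(A, bp)
  C <- compute_capacitance(A, L, bp)
  C0 <- bp$epsilon * bp$eps0 * bp$A0 / bp$L0
  out <- data.frame(t = field$t, A = A, L = L, C = C)
  if (cfg$mode == "vclamp") {
    out$I_C <- cap_current_from_C(C, field$t, cfg$V0)
    out$V <- rep(cfg$V0, nt)
  } else {
    cc <- constant_charge_voltage(C, if (is.null(cfg$C0)) C[1] else cfg$C0,
                                  cfg$V0)
    out$V_exact <- cc$exact
    out$V_approx <- cc$approx
  }
  attr(out, "A0") <- bp$A0
  attr(out, "L0") <- bp$L0
  attr(out, "C0") <- C0
  class(out) <- c("electrical_series", class(out))
  out
}

# V * dC/dt by centred differences, one-sided at the ends
cap_current_from_C <- function(C, t, V) {
  n <- length(C)
  if (n < 3L) stop("need at least 3 samples to differentiate C(t)")
  dC <- numeric(n)
  dC[2:(n - 1)] <- (C[3:n] - C[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dC[1] <- (C[2] - C[1]) / (t[2] - t[1])
  dC[n] <- (C[n] - C[n - 1]) / (t[n] - t[n - 1])
  V * dC
}

#' Capacitive current under voltage clamp
#'
#' `I_C = V dC/dt`, the current required to hold a membrane at voltage `V`
#' while its capacitance changes. Linear in `V` with zero intercept.
#'
#' @param series An [electrical_series()] (or any data frame with uniform
#'   `t` and `C` columns).
#' @param cfg A [voltage_clamp_config()] in `"vclamp"` mode.
#' @return Numeric current series (A).
#' @export
capacitive_current <- function(series, cfg) {
  stopifnot(is.data.frame(series), all(c("t", "C") %in% names(series)),
            inherits(cfg, "voltage_clamp_config"))
  if (cfg$mode != "vclamp")
    stop("capacitive_current() requires voltage-clamp mode")
  dt <- diff(series$t)
  if (length(dt) && diff(range(dt)) > 1e-9 * mean(dt))
    stop("capacitive_current() requires uniformly sampled C(t)")
  cap_current_from_C(series$C, series$t, cfg$V0)
}

constant_charge_voltage <- function(C, C0, V0) {
  if (any(C <= 0)) stop("capacitance must be positive")
  list(exact = V0 * C0 / C,
       approx = V0 * (1 - (C - C0) / C0))
}

#' Membrane voltage under current clamp (constant charge)
#'
#' With the membrane resistance effectively infinite, the stored charge
#' `Q = C V` is constant during the stimulus, so the exact voltage is
#' `V(t) = V0 C0 / C(t)`. For small capacitance changes this is
#' approximated by `V(t) = V0 (1 - (C - C0)/C0)`; both are returned, and
#' they agree within 1% whenever `|dC/C0| < 1%`.
#'
#' @param series An [electrical_series()] or data frame with a `C` column.
#' @param cfg A [voltage_clamp_config()]; `C0` defaults to `C` at the first
#'   sample.
#' @return Data frame with columns `t` (if available), `V_exact`,
#'   `V_approx`.
#' @export
current_clamp_voltage <- function(series, cfg) {
  stopifnot(is.data.frame(series), "C" %in% names(series),
            inherits(cfg, "voltage_clamp_config"))
  C0 <- if (is.null(cfg$C0)) series$C[1] else cfg$C0
  cc <- constant_charge_voltage(series$C, C0, cfg$V0)
  out <- data.frame(V_exact = cc$exact, V_approx = cc$approx)
  if ("t" %in% names(series)) out <- cbind(t = series$t, out)
  out
}
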