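#' @title Interfacial-wave dynamics of a planar bilayer
#'
#' @description
#' The bilayer is treated as a fluid interface clamped at its rim,
#' `u(-d/2, t) = u(d/2, t) = 0`, carrying a standing displacement wave of
#' wavelength `2d` (spatial frequency `q = pi/d`). Reduction of the
#' incompressible Navier--Stokes equation under the assumptions of purely
#' axial displacement and in-plane symmetry, with the interfacial pressure
#' disturbance decaying evanescently into the bulk as `exp(-q z)`, gives the
#' equation of motion for the cross-sectional displacement `u(x, t)`:
#'
#' \deqn{\rho \frac{\partial v}{\partial t} =
#'   2 \eta \frac{\partial^2 v}{\partial x^2} +
#'   q \left( P + 2 \gamma \frac{\partial^2 u}{\partial x^2} \right), \quad
#'   v = \frac{\partial u}{\partial t}}
#'
#' where `P` is the total trans-bilayer pressure (hydrostatic plus gated
#' radiation force). At rest the bracket vanishes, giving the equilibrium
#' profile as the solution of `2 gamma u'' = -P0` — a parabola in `x`.
#'
#' @name bilayer-dynamics
NULL

new_displacement_field <- function(x, t, u, v, q, d) {
  structure(list(x = x, t = t, u = u, v = v, q = q, d = d),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("Displacement field\n")
  cat(sprintf("  grid   : %d nodes on [%g, %g] um\n", length(x$x),
              min(x$x) * 1e6, max(x$x) * 1e6))
  cat(sprintf("  times  : %d samples on [%g, %g] ms\n", length(x$t),
              min(x$t) * 1e3, max(x$t) * 1e3))
  cat(sprintf("  q (=pi/d): %g 1/m\n", x$q))
  u0 <- center_displacement(x)
  cat(sprintf("  centre displacement: %g ... %g um\n",
              min(u0) * 1e6, max(u0) * 1e6))
  invisible(x)
}

#' Centre displacement of a field
#'
#' @param field A `displacement_field`.
#' @return Numeric vector `u(0, t)` (m), one value per stored time.
#' @export
center_displacement <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  i0 <- which.min(abs(field$x))
  field$u[, i0]
}

#' Equilibrium bilayer profile under hydrostatic pressure
#'
#' Solves the linear boundary-value problem `2 gamma u'' = -P0` with the
#' clamped-rim condition `u(-d/2) = u(d/2) = 0` on a uniform grid by a
#' second-order finite-difference (tridiagonal) solve. The resting surface
#' area `A0` is computed from the profile by [compute_area()] and stored in
#' the returned parameter set.
#'
#' @param bp A [bilayer_parameters()] object.
#' @param P0 Hydrostatic pressure (N/m^2).
#' @param settings A [solver_settings()] object (grid resolution).
#' @return A list with components `field` (single-time `displacement_field`),
#'   `bp` (`bp` with `A0` populated) and `residual` (max absolute residual of
#'   the discretized equation, N/m^2).
#' @examples
#' bp <- bilayer_parameters(d = 120e-6, gamma = 0.8e-3)
#' eq <- solve_equilibrium(bp, P0 = -70)
#' center_displacement(eq$field) * 1e6  # ~ -78.75 um
#' @export
solve_equilibrium <- function(bp, P0, settings = solver_settings()) {
  stopifnot(inherits(bp, "bilayer_parameters"),
            is.numeric(P0), length(P0) == 1L, is.finite(P0),
            inherits(settings, "solver_settings"))
  n <- settings$n_nodes
  x <- seq(-bp$d / 2, bp$d / 2, length.out = n)
  h <- x[2] - x[1]
  m <- n - 2L                           # interior nodes
  # tridiagonal system for 2*gamma * (u[i-1]-2u[i]+u[i+1])/h^2 = -P0
  rhs <- rep(-P0 * h^2 / (2 * bp$gamma), m)
  u_int <- solve_tridiag(rep(1, m - 1), rep(-2, m), rep(1, m - 1), rhs)
  u <- c(0, u_int, 0)
  # residual of the discretized operator, reported in pressure units
  res <- 2 * bp$gamma * diff(diff(u)) / h^2 + P0
  residual <- max(abs(res))
  if (!all(is.finite(u)) || residual > 1e-6 * max(1, abs(P0)))
    stop(sprintf(paste0("equilibrium boundary-value solve did not converge ",
                        "(n_nodes = %d, residual = %.3g N/m^2)"),
                 n, residual))
  field <- new_displacement_field(x, 0, matrix(u, nrow = 1),
                                  matrix(0, nrow = 1, ncol = n),
                                  q = pi / bp$d, d = bp$d)
  bp <- set_resting_area(bp, compute_area(field, 1L))
  list(field = field, bp = bp, residual = residual)
}

# Thomas algorithm; a = sub-, b = main, c = super-diagonal
solve_tridiag <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  if (n > 1) {
    for (i in 2:n) {
      den <- b[i] - a[i - 1] * cp[i - 1]
      cp[i] <- if (i < n) c[i] / den else 0
      dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / den
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Dynamic bilayer displacement under a pressure program
#'
#' Integrates the interfacial-wave equation (see [bilayer-dynamics]) by the
#' method of lines: second-order central differences on a uniform grid and a
#' stiff implicit integrator (`deSolve::lsoda` with a banded Jacobian on the
#' interleaved `(u, v)` state). The initial condition is the equilibrium
#' profile at `prog$P0` with zero velocity. For ideal-step programs the
#' integration is restarted at the onset and offset times so the
#' discontinuous forcing is never stepped across.
#'
#' @param bp A [bilayer_parameters()] object.
#' @param med A [medium_properties()] object.
#' @param prog A [pressure_program()] object.
#' @param settings A [solver_settings()] object.
#' @param t_end Final time (s). Defaults to `min(t_off, ...) + 15 ms` past
#'   the last pressure edge inside the window, covering the damped
#'   transients for typical parameter sets; pass explicitly for slow
#'   (large-diameter) bilayers.
#' @param t_start Initial time (s), default 0.
#' @return A `displacement_field` with matrices `u`, `v` of size
#'   `length(t) x n_nodes`.
#' @examples
#' \donttest{
#' bp <- bilayer_parameters(d = 120e-6, gamma = 0.8e-3)
#' fld <- solve_dynamics(bp, medium_properties(),
#'                       pressure_program(-70, 0.15, t_on = 0),
#'                       solver_settings(n_nodes = 101), t_end = 5e-3)
#' }
#' @export
solve_dynamics <- function(bp, med, prog, settings = solver_settings(),
                           t_end = NULL, t_start = 0) {
  stopifnot(inherits(bp, "bilayer_parameters"),
            inherits(med, "medium_properties"),
            inherits(prog, "pressure_program"),
            inherits(settings, "solver_settings"))
  if (is.null(t_end)) {
    last_edge <- if (is.finite(prog$t_off)) prog$t_off else prog$t_on
    t_end <- last_edge + 15e-3
  }
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'")

  n <- settings$n_nodes
  eqm <- solve_equilibrium(bp, prog$P0, settings)
  x <- eqm$field$x
  h <- x[2] - x[1]
  q <- pi / bp$d
  u0 <- eqm$field$u[1, ]

  times <- seq(t_start, t_end, by = settings$dt_out)
  # interleaved state (u1, v1, u2, v2, ...) over interior nodes
  idx_u <- seq(1L, 2L * (n - 2L), by = 2L)
  idx_v <- idx_u + 1L
  rho <- med$rho; eta <- med$eta; gam <- bp$gamma
  lap <- function(w) {
    wfull <- c(0, w, 0)
    (wfull[1:(n - 2)] - 2 * w + wfull[3:n]) / h^2
  }
  rhs <- function(t, y, parms) {
    u <- y[idx_u]; v <- y[idx_v]
    P <- total_pressure(prog, t)
    dv <- (2 * eta * lap(v) + q * (P + 2 * gam * lap(u))) / rho
    dy <- numeric(length(y))
    dy[idx_u] <- v
    dy[idx_v] <- dv
    list(dy)
  }
  y0 <- numeric(2L * (n - 2L))
  y0[idx_u] <- u0[2:(n - 1)]

  # split at forcing discontinuities for ideal-step programs
  edges <- numeric(0)
  if (is.null(prog$envelope))
    edges <- c(prog$t_on, prog$t_off)
  edges <- sort(unique(edges[is.finite(edges) & edges > t_start &
                               edges < t_end]))
  bounds <- c(t_start, edges, t_end)

  out_t <- times
  fuzz <- settings$dt_out * 1e-6
  sol <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  y <- y0
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    io <- which(out_t >= lo - fuzz & out_t <= hi + fuzz)
    tt <- sort(c(lo, out_t[io], hi))
    tt <- tt[c(TRUE, diff(tt) > fuzz)]     # collapse near-duplicates
    seg <- deSolve::lsoda(y, tt, rhs, parms = NULL,
                          rtol = settings$rtol, atol = settings$atol,
                          jactype = "bandint", bandup = 3L, banddown = 3L,
                          maxsteps = 100000L)
    if (attr(seg, "istate")[1] < 0)
      stop("stiff integrator failed in solve_dynamics (segment ", k, ")")
    ymat <- seg[, -1, drop = FALSE]
    if (any(!is.finite(ymat))) stop("non-finite values in PDE solution")
    # nearest integrator output row for each requested sample
    pos <- findInterval(out_t[io], seg[, 1])
    pos <- pmax(pos, 1L)
    up <- pmin(pos + 1L, nrow(seg))
    nearer <- abs(seg[up, 1] - out_t[io]) < abs(seg[pos, 1] - out_t[io])
    pos[nearer] <- up[nearer]
    sol[io, ] <- ymat[pos, , drop = FALSE]
    y <- ymat[nrow(ymat), ]
  }

  u <- cbind(0, sol[, idx_u, drop = FALSE], 0)
  v <- cbind(0, sol[, idx_v, drop = FALSE], 0)
  new_displacement_field(x, out_t, u, v, q = q, d = bp$d)
}

#' Fundamental-mode frequency and damping of the interfacial wave
#'
#' Small-amplitude analysis of the equation of motion for the fundamental
#' standing-wave mode `sin(q (x + d/2))`, `q = pi/d`, gives a damped
#' harmonic oscillator with natural angular frequency
#' `omega0 = sqrt(2 gamma q^3 / rho)` and envelope decay rate
#' `eta q^2 / rho`. Used as an analytic cross-check of the numerical
#' solver.
#'
#' @param bp A [bilayer_parameters()] object.
#' @param med A [medium_properties()] object.
#' @return List with `frequency` (Hz, undamped), `damping` (1/s),
#'   `frequency_damped` (Hz, the observed oscillation frequency
#'   `sqrt(omega0^2 - damping^2)/2pi`; `NA` if overdamped).
#' @examples
#' modal_characteristics(bilayer_parameters(120e-6, 0.8e-3),
#'                       medium_properties())
#' @export
modal_characteristics <- function(bp, med) {
  stopifnot(inherits(bp, "bilayer_parameters"),
            inherits(med, "medium_properties"))
  q <- pi / bp$d
  omega0 <- sqrt(2 * bp$gamma * q^3 / med$rho)
  damping <- med$eta * q^2 / med$rho
  wd2 <- omega0^2 - damping^2
  list(frequency = omega0 / (2 * pi),
       damping = damping,
       frequency_damped = if (wd2 > 0) sqrt(wd2) / (2 * pi) else NA_real_)
}
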