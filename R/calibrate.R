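#' Fast modal prediction of the voltage-clamp response observables
#'
#' Closed-form fundamental-mode approximation of the full pipeline, used as
#' the forward map for parameter calibration where thousands of model
#' evaluations are needed. For a given diameter the centre displacement
#' relaxes from the equilibrium at `P0` to the equilibrium at `P0 + P_US`
#' as an underdamped oscillator with the [modal_characteristics()]
#' frequency and damping; the area follows the closed-form
#' paraboloid-of-revolution expression, capacitance the constant-volume
#' quadratic law `C = C0 (A/A0)^2`, and the amplitude observable is the
#' peak magnitude of `V dC/dt` sampled at 100 kHz.
#'
#' @param d Bilayer diameter(s) (m).
#' @param gamma Interfacial tension (N/m).
#' @param P0 Hydrostatic pressure (N/m^2), nonzero.
#' @param P_US Radiation-force pressure (N/m^2).
#' @param med A [medium_properties()].
#' @param L0,epsilon Dielectric geometry, as in [bilayer_parameters()].
#' @param V0 Holding potential (V) for the amplitude observable.
#' @param sample_rate Sampling rate (Hz) of the emulated current.
#' @return Data frame with one row per diameter: `d`, `C` (resting
#'   capacitance, F), `amplitude` (peak |I_C|, A), `f` (Hz), `alpha` (1/s).
#' @export
modal_response_curve <- function(d, gamma, P0, P_US,
                                 med = medium_properties(),
                                 L0 = 4e-9, epsilon = 2, V0 = -0.2,
                                 sample_rate = 1e5) {
  stopifnot(is.numeric(d), all(d > 0), gamma > 0)
  if (P0 == 0) stop("modal amplitude observable requires nonzero P0")
  eps0 <- 8.8541878128e-12
  out <- lapply(d, function(dd) {
    a_rim <- dd / 2
    q <- pi / dd
    omega0 <- sqrt(2 * gamma * q^3 / med$rho)
    alpha <- med$eta * q^2 / med$rho
    wd2 <- omega0^2 - alpha^2
    u_eq <- P0 * dd^2 / (16 * gamma)
    u_ss <- (P0 + P_US) * dd^2 / (16 * gamma)
    A0 <- paraboloid_area(abs(u_eq), a_rim)
    C0 <- epsilon * eps0 * A0 / L0
    t_sim <- seq(0, 12 / alpha, by = 1 / sample_rate)
    u0 <- if (wd2 > 0) {
      wd <- sqrt(wd2)
      u_ss + (u_eq - u_ss) * exp(-alpha * t_sim) *
        (cos(wd * t_sim) + (alpha / wd) * sin(wd * t_sim))
    } else {
      r1 <- -alpha + sqrt(-wd2); r2 <- -alpha - sqrt(-wd2)
      u_ss + (u_eq - u_ss) * (r2 * exp(r1 * t_sim) - r1 * exp(r2 * t_sim)) /
        (r2 - r1)
    }
    A <- paraboloid_area(abs(u0), a_rim)
    C <- C0 * (A / A0)^2
    I <- V0 * c(diff(C), 0) * sample_rate
    data.frame(d = dd, C = C0, amplitude = max(abs(I)),
               f = omega0 / (2 * pi), alpha = alpha)
  })
  do.call(rbind, out)
}

# closed-form lateral area of a paraboloid of revolution, depth h, rim a
paraboloid_area <- function(h, a) {
  ifelse(h <= .Machine$double.eps * a, pi * a^2,
         (pi * a / (6 * h^2)) * ((a^2 + 4 * h^2)^1.5 - a^3))
}

#' Calibrate model parameters against response-vs-capacitance observations
#'
#' Least-squares estimation of a subset of `gamma`, `P0`, `P_US` from
#' observed (capacitance, amplitude, frequency, damping) tuples, the
#' summary observables of voltage-clamp responses across bilayers of
#' different diameters. For each candidate parameter set the observed
#' capacitance is inverted to a diameter (capacitance is monotone in
#' diameter at fixed tension and pressure) and the predicted amplitude,
#' frequency and damping from [modal_response_curve()] are compared with
#' the observations; the misfit is summed over log-scale residuals of the
#' three observables and minimised with `optim`.
#'
#' @param observed Data frame with columns `C` (F), `amplitude` (A,
#'   magnitudes are used), `f` (Hz), `alpha` (1/s); at least 3 rows and at
#'   least as many rows as free parameters.
#' @param free Character vector, subset of `c("gamma", "P0", "P_US")`.
#' @param start Named list of starting values for all three parameters
#'   (fixed ones are held at their start value).
#' @param med A [medium_properties()].
#' @param L0,epsilon,V0 Forwarded to [modal_response_curve()].
#' @return List with `par` (named estimates of the free parameters),
#'   `residuals` (per-observation, per-observable log residual matrix),
#'   `rss`, and the `optim` convergence code.
#' @export
calibrate_parameters <- function(observed, free = "gamma",
                                 start = list(gamma = 1e-3, P0 = -50,
                                              P_US = 0.1),
                                 med = medium_properties(),
                                 L0 = 4e-9, epsilon = 2, V0 = -0.2) {
  stopifnot(is.data.frame(observed),
            all(c("C", "amplitude", "f", "alpha") %in% names(observed)))
  free <- match.arg(free, c("gamma", "P0", "P_US"), several.ok = TRUE)
  if (nrow(observed) < max(3L, length(free)))
    stop(sprintf(paste0("under-determined calibration: %d observation(s) ",
                        "for %d free parameter(s); need at least %d"),
                 nrow(observed), length(free), max(3L, length(free))))
  if (any(observed$C <= 0)) stop("observed capacitances must be positive")

  pars <- unlist(start[c("gamma", "P0", "P_US")])
  # log-scale for the positive parameters, linear for P0
  encode <- function(p) {
    v <- c(gamma = log(p[["gamma"]]), P0 = p[["P0"]],
           P_US = log(max(p[["P_US"]], 1e-12)))
    v[free]
  }
  decode <- function(theta) {
    p <- pars
    for (nm in free) {
      p[[nm]] <- if (nm == "P0") theta[[nm]] else exp(theta[[nm]])
    }
    p
  }
  resid_mat <- function(p) {
    d <- vapply(observed$C, function(Ci)
      invert_capacitance(Ci, p[["gamma"]], p[["P0"]], L0, epsilon),
      numeric(1))
    pred <- modal_response_curve(d, p[["gamma"]], p[["P0"]], p[["P_US"]],
                                 med = med, L0 = L0, epsilon = epsilon,
                                 V0 = V0)
    cbind(amplitude = log(abs(observed$amplitude)) - log(pred$amplitude),
          f = log(observed$f) - log(pred$f),
          alpha = log(observed$alpha) - log(pred$alpha))
  }
  obj <- function(theta) {
    names(theta) <- free
    p <- decode(theta)
    r <- tryCatch(resid_mat(p), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e10)
    sum(r^2)
  }
  theta0 <- encode(pars)
  opt <- if (length(free) == 1L) {
    o <- stats::optim(theta0, obj, method = "Brent",
                      lower = theta0 - 6, upper = theta0 + 6)
    o
  } else {
    stats::optim(theta0, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
  }
  theta <- opt$par
  names(theta) <- free
  p_hat <- decode(theta)
  list(par = p_hat[free], residuals = resid_mat(p_hat), rss = opt$value,
       convergence = opt$convergence)
}

# diameter whose equilibrium (paraboloid) capacitance equals C
invert_capacitance <- function(C, gamma, P0, L0, epsilon) {
  eps0 <- 8.8541878128e-12
  cap <- function(d) {
    h <- abs(P0) * d^2 / (16 * gamma)
    A0 <- paraboloid_area(h, d / 2)
    epsilon * eps0 * (A0 / L0) * (1)  # C = eps eps0 A0 / L0 at rest
  }
  f <- function(d) cap(d) - C
  lo <- 1e-6; hi <- 1e-2
  if (f(lo) > 0 || f(hi) < 0) stop("capacitance outside invertible range")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
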