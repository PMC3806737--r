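#' Sampled electrophysiology trace
#'
#' A uniformly sampled signal (current, voltage or interface velocity) with
#' recording metadata. The default sampling rate of the emulated recordings
#' is 100 kHz with a 10-kHz low-pass filter.
#'
#' @param t Sample times (s), strictly increasing and uniform.
#' @param y Signal values.
#' @param y_units One of `"pA"`, `"mV"`, `"mm/s"`.
#' @param meta Named list of metadata. Recognised keys: `v_hold` (holding
#'   potential, V), `c0` (baseline capacitance, F), `t_on`, `t_off`
#'   (stimulus window, s), `n_avg` (averaging count), `truth` (generator
#'   parameters, for synthetic traces).
#' @return Object of class `trace_record`.
#' @export
trace_record <- function(t, y, y_units = c("pA", "mV", "mm/s"),
                         meta = list()) {
  y_units <- match.arg(y_units)
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y),
            length(t) >= 2L, is.list(meta))
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) stop("sampling must be uniform")
  for (k in c("t_on", "t_off")) {
    if (!is.null(meta[[k]]) &&
        (meta[[k]] < t[1] - mean(dt) || meta[[k]] > t[length(t)] + mean(dt)))
      stop(sprintf("meta$%s lies outside the record", k))
  }
  structure(list(t = t, y = y, y_units = y_units, meta = meta),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("Trace record: %d samples at %.4g kHz, units %s\n",
              length(x$t), 1e-3 / mean(diff(x$t)), x$y_units))
  if (!is.null(x$meta$t_on))
    cat(sprintf("  stimulus: %g .. %g ms\n", x$meta$t_on * 1e3,
                if (is.null(x$meta$t_off)) NA else x$meta$t_off * 1e3))
  if (!is.null(x$meta$v_hold))
    cat(sprintf("  holding potential: %g mV\n", x$meta$v_hold * 1e3))
  if (!is.null(x$meta$c0))
    cat(sprintf("  baseline capacitance: %g pF\n", x$meta$c0 * 1e12))
  invisible(x)
}

trace_dt <- function(trace) mean(diff(trace$t))

# baseline statistics from the pre-stimulus segment (NULL if absent)
baseline_stats <- function(trace) {
  if (is.null(trace$meta$t_on)) return(NULL)
  pre <- trace$t < trace$meta$t_on
  if (sum(pre) < 2L) return(NULL)
  list(mean = mean(trace$y[pre]), sd = stats::sd(trace$y[pre]),
       n = sum(pre))
}

#' Fit an exponentially decaying sinusoid to an On or Off transient
#'
#' Fits `a * exp(-alpha t) * sin(2 pi f t + phi)` with `t` measured from
#' the stimulus onset (`window = "on"`) or offset (`"off"`) by nonlinear
#' least squares (Levenberg--Marquardt). Initialisation is deterministic:
#' `f` from the dominant FFT peak of the windowed segment, `alpha` from a
#' log-linear fit to the analytic-signal envelope, and `(a, phi)` from the
#' linear subproblem at the initial `(f, alpha)`. The fit window runs from
#' the stimulus edge to the point where the envelope estimate falls below
#' twice the pre-stimulus baseline SD (minimum two oscillation periods).
#'
#' If the signal is indistinguishable from noise (peak deviation or fitted
#' amplitude below twice the baseline SD) the result is flagged
#' `no_oscillation` — the behaviour of highly damped (e.g. cholesterol)
#' membranes.
#'
#' @param trace A [trace_record()]; `meta$t_on` / `meta$t_off` must be set
#'   for the corresponding window.
#' @param window `"on"`, `"off"`, or a numeric `c(start, end)` in seconds
#'   (absolute trace time; `t = 0` of the model is then `start`).
#' @return Object of class `damped_sine_fit`: fields `a`, `f`, `alpha`,
#'   `phi` (phase wrapped to (-pi, pi\]), standard errors `se` (one SD per
#'   parameter, from the fit covariance), `residual_rms`, `window`,
#'   `no_oscillation`, `baseline_sd` and the underlying `nls` object.
#' @examples
#' tr <- generate_onoff_trace(synthetic_spec(
#'   on_params = list(a = 800e-12, f = 900, alpha = 700, phi = -0.21),
#'   noise_sd = 0, lowpass_hz = NULL))
#' fit_damped_sine(tr, "on")
#' @export
fit_damped_sine <- function(trace, window = c("on", "off")) {
  stopifnot(inherits(trace, "trace_record"))
  bl <- baseline_stats(trace)
  baseline_sd <- if (is.null(bl)) 0 else bl$sd
  baseline_mean <- if (is.null(bl)) 0 else bl$mean

  half_dt <- trace_dt(trace) / 2
  if (is.numeric(window)) {
    stopifnot(length(window) == 2L, window[2] > window[1])
    t0 <- window[1]; t1 <- window[2]
  } else {
    window <- match.arg(window)
    edge <- switch(window, on = trace$meta$t_on, off = trace$meta$t_off)
    if (is.null(edge))
      stop(sprintf("meta$t_%s is required for window = \"%s\"",
                   window, window))
    t0 <- edge
    # the On window stops short of the offset edge (exclusive)
    t1 <- if (window == "on" && !is.null(trace$meta$t_off) &&
              is.finite(trace$meta$t_off)) trace$meta$t_off - half_dt
          else trace$t[length(trace$t)]
  }
  sel <- trace$t >= t0 - half_dt & trace$t <= t1 + half_dt / 2
  tt <- trace$t[sel] - t0
  yy <- trace$y[sel] - baseline_mean
  if (length(tt) < 8L) stop("fit window contains too few samples")

  flag_result <- function() {
    structure(list(a = 0, f = NA_real_, alpha = NA_real_, phi = NA_real_,
                   se = c(a = NA_real_, f = NA_real_, alpha = NA_real_,
                          phi = NA_real_),
                   residual_rms = stats::sd(yy), window = c(t0, t1),
                   no_oscillation = TRUE, baseline_sd = baseline_sd,
                   fit = NULL),
              class = "damped_sine_fit")
  }
  thresh <- 2 * baseline_sd
  if (max(abs(yy)) <= max(thresh, .Machine$double.eps * 100))
    return(flag_result())

  ini <- damped_sine_init(tt, yy, thresh)
  if (is.null(ini)) return(flag_result())

  # truncate window where envelope falls below noise, keep >= 2 periods
  t_env <- ini$t_noise
  t_min <- 2 / ini$f
  t_cut <- max(t_env, t_min)
  keep <- tt <= t_cut
  if (sum(keep) >= 16L) { tt2 <- tt[keep]; yy2 <- yy[keep] } else {
    tt2 <- tt; yy2 <- yy
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy2 ~ a * exp(-alpha * tt2) * sin(2 * pi * f * tt2 + phi),
      start = list(a = ini$a, f = ini$f, alpha = ini$alpha, phi = ini$phi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop(sprintf(paste0("damped-sine fit did not converge (initial a=%.3g, ",
                        "f=%.3g Hz, alpha=%.3g 1/s, phi=%.3g rad)"),
                 ini$a, ini$f, ini$alpha, ini$phi))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  # canonical form: f, alpha positive; (a, phi) and (-a, phi + pi) are the
  # same curve, so fold the phase into (-pi/2, pi/2] and carry the sign on
  # the amplitude (the convention of the published fits)
  if (cf[["f"]] < 0) {
    cf[["f"]] <- -cf[["f"]]; cf[["phi"]] <- -cf[["phi"]]
    cf[["a"]] <- -cf[["a"]]
  }
  phi <- wrap_phase(cf[["phi"]])
  a <- cf[["a"]]
  if (phi > pi / 2) { phi <- phi - pi; a <- -a }
  if (phi <= -pi / 2) { phi <- phi + pi; a <- -a }
  if (abs(a) < thresh) return(flag_result())
  structure(list(a = a, f = cf[["f"]], alpha = cf[["alpha"]], phi = phi,
                 se = c(a = unname(se["a"]), f = unname(se["f"]),
                        alpha = unname(se["alpha"]),
                        phi = unname(se["phi"])),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 window = c(t0, t0 + max(tt2)),
                 no_oscillation = FALSE, baseline_sd = baseline_sd,
                 fit = fit),
            class = "damped_sine_fit")
}

wrap_phase <- function(phi) {
  phi <- (phi + pi) %% (2 * pi) - pi
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

# deterministic initial estimates for the damped-sine fit
damped_sine_init <- function(tt, yy, noise_thresh) {
  n <- length(yy)
  dt <- tt[2] - tt[1]
  # dominant FFT frequency (exclude DC)
  sp <- Mod(stats::fft(yy - mean(yy)))[seq_len(floor(n / 2))]
  freqs <- (seq_along(sp) - 1) / (n * dt)
  k <- which.max(sp[-1]) + 1L
  f0 <- freqs[k]
  if (!is.finite(f0) || f0 <= 0) return(NULL)
  # analytic-signal envelope via FFT; log-linear decay fit above noise
  env <- Mod(analytic_signal(yy - mean(yy)))
  use <- env > max(noise_thresh, 1e-3 * max(env))
  t_noise <- if (any(!use)) tt[which.max(!use)] else max(tt)
  use <- use & tt <= max(t_noise, 4 / f0)
  if (sum(use) < 4L) use <- seq_len(min(n, 32L))
  co <- stats::coef(stats::lm(log(env[use]) ~ tt[use]))
  alpha0 <- max(-co[2], f0 / 50)
  # linear subproblem for amplitude and phase at (f0, alpha0)
  e <- exp(-alpha0 * tt)
  X <- cbind(e * sin(2 * pi * f0 * tt), e * cos(2 * pi * f0 * tt))
  ab <- tryCatch(stats::lm.fit(X, yy)$coefficients,
                 error = function(e) c(max(abs(yy)), 0))
  a0 <- sqrt(sum(ab^2))
  phi0 <- atan2(ab[[2]], ab[[1]])
  list(a = unname(a0), f = unname(f0), alpha = unname(alpha0),
       phi = unname(phi0), t_noise = unname(t_noise))
}

analytic_signal <- function(y) {
  n <- length(y)
  Y <- stats::fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(Y * h, inverse = TRUE) / n
}

#' @export
print.damped_sine_fit <- function(x, ...) {
  if (x$no_oscillation) {
    cat("Damped-sine fit: no oscillation above noise",
        sprintf("(baseline SD %.3g)\n", x$baseline_sd))
    return(invisible(x))
  }
  cat("Damped-sine fit  a * exp(-alpha t) * sin(2 pi f t + phi)\n")
  cat(sprintf("  a     = %.4g +/- %.2g\n", x$a, x$se["a"]))
  cat(sprintf("  f     = %.4g +/- %.2g Hz\n", x$f, x$se["f"]))
  cat(sprintf("  alpha = %.4g +/- %.2g 1/s\n", x$alpha, x$se["alpha"]))
  cat(sprintf("  phi   = %.4g +/- %.2g rad\n", x$phi, x$se["phi"]))
  cat(sprintf("  residual RMS %.4g over window [%.4g, %.4g] ms\n",
              x$residual_rms, x$window[1] * 1e3, x$window[2] * 1e3))
  invisible(x)
}

#' Net capacitance change from a damped-sine fit
#'
#' Integrating the fitted transient `a exp(-alpha t) sin(2 pi f t + phi)`
#' from 0 to infinity and dividing by the holding potential gives the net
#' capacitance change in closed form:
#' \deqn{\Delta C = \frac{a}{V}\,
#'   \frac{\omega \cos\varphi + \alpha \sin\varphi}{\alpha^2 + \omega^2},
#'   \quad \omega = 2 \pi f.}
#'
#' @param fit A `damped_sine_fit`.
#' @param V Holding potential (V), nonzero.
#' @return Capacitance change (F). Zero for a flagged no-oscillation fit.
#' @export
net_dC_from_fit <- function(fit, V) {
  stopifnot(inherits(fit, "damped_sine_fit"),
            is.numeric(V), length(V) == 1L, is.finite(V))
  if (V == 0) stop("holding potential V must be nonzero")
  if (fit$no_oscillation || fit$a == 0) return(0)
  omega <- 2 * pi * fit$f
  (fit$a / V) * (omega * cos(fit$phi) + fit$alpha * sin(fit$phi)) /
    (fit$alpha^2 + omega^2)
}

#' Net capacitance change by direct integration of the current
#'
#' Subtracts the pre-stimulus baseline current, integrates cumulatively
#' (trapezoid rule) and divides by the holding potential to obtain
#' `C(t) - C0`; the reported net change is the mean over the final 1 ms of
#' the stimulus.
#'
#' @param trace A [trace_record()] in current units with `meta$v_hold`,
#'   `meta$t_on` and `meta$t_off` set and a pre-stimulus baseline segment.
#' @param window_s Width of the end-of-pulse averaging window (s),
#'   default 1 ms.
#' @return List with `dC` (net change, F) and `C_t` (data frame `t`,
#'   `dC`: the capacitance change as a function of time, F).
#' @export
net_dC_direct <- function(trace, window_s = 1e-3) {
  stopifnot(inherits(trace, "trace_record"))
  V <- trace$meta$v_hold
  if (is.null(V) || V == 0) stop("meta$v_hold must be set and nonzero")
  if (is.null(trace$meta$t_on) || is.null(trace$meta$t_off))
    stop("meta$t_on and meta$t_off are required")
  bl <- baseline_stats(trace)
  if (is.null(bl)) stop("no pre-stimulus baseline segment in the trace")
  y_pa <- switch(trace$y_units, pA = trace$y * 1e-12,
                 stop("net_dC_direct() expects a current trace in pA"))
  i0 <- bl$mean * 1e-12
  dCt <- cumtrapz(trace$t, y_pa - i0) / V
  t_off <- trace$meta$t_off
  w <- trace$t >= (t_off - window_s) & trace$t <= t_off
  if (!any(w)) stop("averaging window does not overlap the record")
  list(dC = mean(dCt[w]), C_t = data.frame(t = trace$t, dC = dCt))
}

cumtrapz <- function(t, y) {
  c(0, cumsum(0.5 * diff(t) * (y[-1] + y[-length(y)])))
}

#' Power-law dependence of response amplitude on capacitance
#'
#' Fits the normalisation function `F_C(C) = k C^beta` to (capacitance,
#' amplitude) points by least squares in log space. Amplitudes are taken in
#' magnitude; a sign convention leaving non-positive values is an error.
#'
#' @param points Data frame with columns `C` (F, positive) and `amplitude`.
#' @return Object of class `amplitude_capacitance_law` with `k`, `beta`,
#'   standard errors, the fitted `lm`, and `saturated = TRUE` when exactly
#'   two points determine the two parameters (exact interpolation, not a
#'   validated fit).
#' @export
fit_amplitude_capacitance_law <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("C", "amplitude") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 (C, amplitude) points")
  if (any(points$C <= 0)) stop("capacitances must be positive")
  a <- abs(points$amplitude)
  if (any(a <= 0))
    stop("amplitudes must be nonzero (magnitudes are fitted)")
  fit <- stats::lm(log(a) ~ log(points$C))
  cf <- stats::coef(fit)
  # exact data make the residual-based SEs meaningless; keep them NA-safe
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, 2))
  structure(list(k = exp(cf[[1]]), beta = cf[[2]],
                 se = c(log_k = unname(se[1]), beta = unname(se[2])),
                 saturated = nrow(points) == 2L, fit = fit),
            class = "amplitude_capacitance_law")
}

#' Evaluate an amplitude-capacitance power law
#'
#' @param law An `amplitude_capacitance_law`.
#' @param C Capacitance(s) (F), positive.
#' @return `k * C^beta`.
#' @export
predict_amplitude <- function(law, C) {
  stopifnot(inherits(law, "amplitude_capacitance_law"))
  if (any(C <= 0)) stop("capacitance must be positive")
  law$k * C^law$beta
}

#' @export
print.amplitude_capacitance_law <- function(x, ...) {
  cat(sprintf("Amplitude-capacitance power law: F_C(C) = %.4g * C^%.4g%s\n",
              x$k, x$beta,
              if (x$saturated) "  [saturated fit, unvalidated]" else ""))
  invisible(x)
}

#' Normalise a response amplitude to a reference capacitance
#'
#' `a_n = a * F_C(C0) / F_C(C)`: removes the diameter-driven dependence of
#' the response amplitude on bilayer capacitance so that responses recorded
#' at different capacitances are comparable. At `C = C0` the amplitude is
#' unchanged.
#'
#' @param a Raw amplitude(s).
#' @param C Capacitance(s) at which `a` was measured (F), positive.
#' @param C0 Reference capacitance (F), positive.
#' @param law A fitted `amplitude_capacitance_law`.
#' @return Normalised amplitude(s).
#' @export
normalize_amplitude <- function(a, C, C0, law) {
  stopifnot(inherits(law, "amplitude_capacitance_law"))
  if (any(C <= 0) || C0 <= 0) stop("capacitances must be positive")
  a * predict_amplitude(law, C0) / predict_amplitude(law, C)
}

#' Model-based conversion from capacitance to bilayer perimeter
#'
#' Builds the theoretical capacitance--perimeter relationship by solving the
#' equilibrium model over a range of diameters at fixed tension and
#' hydrostatic pressure, fits a power function `perimeter = k C^beta`, and
#' returns a conversion function. The relationship is monotone increasing
#' in `C`; evaluating outside the modelled capacitance range raises an
#' extrapolation warning.
#'
#' @param d_range Diameters (m) spanning the bilayers of interest; at least
#'   3 values.
#' @param gamma Interfacial tension (N/m).
#' @param P0 Hydrostatic pressure (N/m^2).
#' @param L0,epsilon Passed to [bilayer_parameters()].
#' @param settings [solver_settings()] for the equilibrium solves.
#' @return Object of class `capacitance_perimeter_model`: the power-law
#'   coefficients, the model table (`d`, `perimeter`, `C`), and
#'   `$convert(C)` evaluating the fitted function.
#' @examples
#' m <- capacitance_perimeter_model(c(60e-6, 120e-6, 240e-6),
#'                                  gamma = 0.8e-3, P0 = 0)
#' perimeter_from_capacitance(50e-12, m) * 1e6  # ~ 377 um for a flat bilayer
#' @export
capacitance_perimeter_model <- function(d_range, gamma, P0, L0 = 4e-9,
                                        epsilon = 2,
                                        settings = solver_settings()) {
  stopifnot(is.numeric(d_range), length(d_range) >= 3L, all(d_range > 0))
  d_range <- sort(d_range)
  C <- vapply(d_range, function(d) {
    bp <- bilayer_parameters(d = d, gamma = gamma, L0 = L0,
                             epsilon = epsilon)
    eq <- solve_equilibrium(bp, P0, settings)
    compute_capacitance(eq$bp$A0, L0, bp)
  }, numeric(1))
  tab <- data.frame(d = d_range, perimeter = pi * d_range, C = C)
  fit <- stats::lm(log(perimeter) ~ log(C), data = tab)
  cf <- stats::coef(fit)
  structure(list(k = exp(cf[[1]]), beta = cf[[2]], table = tab,
                 C_range = range(C), gamma = gamma, P0 = P0),
            class = "capacitance_perimeter_model")
}

#' Convert measured capacitance to an estimated bilayer perimeter
#'
#' @param C Capacitance(s) (F), positive.
#' @param model A [capacitance_perimeter_model()].
#' @return Perimeter(s) (m). Warns when `C` lies outside the range of
#'   capacitances used to build the model.
#' @export
perimeter_from_capacitance <- function(C, model) {
  stopifnot(inherits(model, "capacitance_perimeter_model"))
  if (any(C <= 0)) stop("capacitance must be positive")
  if (any(C < model$C_range[1] | C > model$C_range[2]))
    warning("capacitance outside the modelled range; extrapolating the ",
            "fitted power law")
  model$k * C^model$beta
}

#' @export
print.capacitance_perimeter_model <- function(x, ...) {
  cat(sprintf(paste0("Capacitance-perimeter model (gamma = %g mN/m, ",
                     "P0 = %g N/m^2)\n"), x$gamma * 1e3, x$P0))
  cat(sprintf("  perimeter = %.4g * C^%.4g  over C in [%.3g, %.3g] pF\n",
              x$k, x$beta, x$C_range[1] * 1e12, x$C_range[2] * 1e12))
  invisible(x)
}
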