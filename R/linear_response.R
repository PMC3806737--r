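#' Impulse response from a measured or simulated step response
#'
#' The On response to an unmodulated ultrasound pulse is the step response
#' of the (linear) bilayer system; differencing it in time gives the
#' impulse response. One-sided first differences are used so that the
#' cumulative sum of the impulse response reproduces the step response
#' exactly: `h[n] = (y[n] - y[n-1]) / dt` with `y[0] = 0` (the baseline
#' must already be removed from the step segment).
#'
#' @param step_trace A [trace_record()] holding the baseline-subtracted On
#'   segment, uniformly sampled, starting at the stimulus edge.
#' @return Object of class `impulse_response`: `t` (time from onset, s),
#'   `h` (signal units per second), `dt`, `source`.
#' @examples
#' st <- trace_record(t = (0:99) * 1e-5, y = c(0, rep(1, 99)))
#' h <- step_to_impulse(st)
#' max(h$h) * h$dt  # unit step recovered: single impulse of height 1/dt
#' @export
step_to_impulse <- function(step_trace) {
  stopifnot(inherits(step_trace, "trace_record"))
  dt <- diff(step_trace$t)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("step_to_impulse() requires uniform sampling")
  dt <- mean(dt)
  y <- step_trace$y
  h <- c(y[1], diff(y)) / dt
  structure(list(t = step_trace$t - step_trace$t[1], h = h, dt = dt,
                 source = step_trace$y_units),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf(paste0("Impulse response: %d samples, dt = %.3g s, ",
                     "integral %.4g %s\n"),
              length(x$h), x$dt, sum(x$h) * x$dt, x$source))
  invisible(x)
}

#' Predict the response to an arbitrary intensity envelope by convolution
#'
#' Causal discrete convolution of the impulse response with a dimensionless
#' intensity envelope (radiation pressure is proportional to instantaneous
#' intensity): `out[n] = dt * sum_k h[k] envelope[n - k + 1]`. An envelope
#' identically 1 returns the step response. Optionally adds seeded Gaussian
#' noise with the SD of the baseline noise, replicating how measured
#' predictions are compared with recordings.
#'
#' @param h An [step_to_impulse()] result.
#' @param envelope Numeric vector of intensity fractions in \[0, 1\],
#'   sampled on the impulse response's grid, or a `trace_record` with
#'   matching sampling rate.
#' @param noise_sd Optional Gaussian noise SD (signal units), default 0.
#' @param seed Seed for the noise, default 0.
#' @return Numeric vector, same length as the envelope.
#' @export
predict_response <- function(h, envelope, noise_sd = 0, seed = 0L) {
  stopifnot(inherits(h, "impulse_response"))
  if (inherits(envelope, "trace_record")) {
    dt_env <- mean(diff(envelope$t))
    if (abs(dt_env - h$dt) > 1e-9 * h$dt)
      stop("envelope sampling rate does not match the impulse response")
    envelope <- envelope$y
  }
  stopifnot(is.numeric(envelope))
  if (any(envelope < -1e-9 | envelope > 1 + 1e-9))
    stop("envelope values must lie in [0, 1]")
  n <- length(envelope)
  m <- n + length(h$h) - 1L
  H <- stats::fft(c(h$h, numeric(m - length(h$h))))
  E <- stats::fft(c(envelope, numeric(m - n)))
  full <- Re(stats::fft(H * E, inverse = TRUE)) / m
  out <- h$dt * full[seq_len(n)]
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    out <- out + stats::rnorm(n, sd = noise_sd)
  }
  out
}

#' Quadratic rise/fall intensity envelope
#'
#' Intensity rises quadratically from 0 to 1 over `ramp` seconds, holds at
#' 1, and falls quadratically to 0 over `ramp` seconds at the end of the
#' pulse — the modulated-intensity stimulus used to test linear-system
#' predictions.
#'
#' @param ramp Rise and fall duration (s).
#' @param plateau Duration at full intensity (s).
#' @return A function of time-since-onset suitable as the `envelope` of a
#'   [pressure_program()].
#' @export
quadratic_ramp_envelope <- function(ramp, plateau) {
  stopifnot(ramp >= 0, plateau >= 0)
  total <- 2 * ramp + plateau
  function(t) {
    e <- numeric(length(t))
    rise <- t >= 0 & t < ramp
    hold <- t >= ramp & t < ramp + plateau
    fall <- t >= ramp + plateau & t < total
    if (ramp > 0) {
      e[rise] <- (t[rise] / ramp)^2
      e[fall] <- ((total - t[fall]) / ramp)^2
    }
    e[hold] <- 1
    if (ramp == 0) e[t >= 0 & t < total] <- 1
    pmin(pmax(e, 0), 1)
  }
}
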