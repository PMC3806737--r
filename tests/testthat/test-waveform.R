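test_that("trace records enforce uniform, increasing sampling", {
  expect_error(trace_record(c(0, 1e-5, 1.5e-5), c(0, 0, 0)), "uniform")
  expect_error(trace_record(c(0, 0, 1e-5), c(0, 0, 0)), "increasing")
  expect_error(trace_record((0:10) * 1e-5, 0:10, meta = list(t_on = 1)),
               "outside the record")
})

test_that("noiseless damped-sine round trip recovers parameters exactly", {
  p <- fig1_params()
  tr <- generate_onoff_trace(synthetic_spec(on_params = p, noise_sd = 0,
                                            lowpass_hz = NULL))
  fit <- fit_damped_sine(tr, "on")
  expect_false(fit$no_oscillation)
  expect_equal(fit$a, p$a, tolerance = 1e-4)
  expect_equal(fit$f, p$f, tolerance = 1e-4)
  expect_equal(fit$alpha, p$alpha, tolerance = 1e-4)
  expect_equal(fit$phi, p$phi, tolerance = 1e-4)
  # Off transient carries the opposite-sign amplitude
  fit_off <- fit_damped_sine(tr, "off")
  expect_equal(fit_off$a, -p$a, tolerance = 2e-3)
  expect_equal(fit_off$phi, p$phi, tolerance = 2e-2)
})

test_that("fits on noisy traces stay within a few fitted SDs of truth", {
  p <- fig1_params()
  ok <- vapply(1:20, function(s) {
    tr <- generate_onoff_trace(synthetic_spec(on_params = p,
                                              noise_sd = 50,
                                              lowpass_hz = NULL,
                                              seed = s))
    fit <- fit_damped_sine(tr, "on")
    truth <- c(a = p$a, f = p$f, alpha = p$alpha, phi = p$phi)
    est <- c(a = fit$a, f = fit$f, alpha = fit$alpha, phi = fit$phi)
    all(abs(est - truth) <= 3 * fit$se)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a flat or sub-noise trace is flagged as no oscillation", {
  z <- trace_record((0:2499) * 1e-5, rep(0, 2500),
                    meta = list(t_on = 2e-3, t_off = 12e-3))
  expect_true(fit_damped_sine(z, "on")$no_oscillation)
  # noise-only trace: nothing above twice the baseline SD
  set.seed(1)
  n <- trace_record((0:2499) * 1e-5, rnorm(2500, sd = 5),
                    meta = list(t_on = 2e-3, t_off = 12e-3))
  fitn <- fit_damped_sine(n, "on")
  expect_true(fitn$no_oscillation)
})

test_that("net dC closed form equals the improper-integral oracle", {
  # oracle: adaptive quadrature of the transient over a finite horizon
  # long enough that the envelope has fully decayed
  quad_dC <- function(a, f, alpha, phi, V) {
    stats::integrate(function(t) a * exp(-alpha * t) *
                       sin(2 * pi * f * t + phi),
                     0, 40 / alpha, rel.tol = 1e-11,
                     subdivisions = 4000L)$value / V
  }
  mk_fit <- function(a, f, alpha, phi)
    structure(list(a = a, f = f, alpha = alpha, phi = phi,
                   no_oscillation = FALSE), class = "damped_sine_fit")
  # published-scale example
  expect_equal(net_dC_from_fit(mk_fit(800e-12, 900, 700, -0.21), -0.2) *
                 1e12, -0.66, tolerance = 6e-3)
  expect_equal(net_dC_from_fit(mk_fit(0, 900, 700, -0.21), -0.2), 0)
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 1e-11, 1e-9) * sample(c(-1, 1), 1)
    f <- runif(1, 100, 3000); al <- runif(1, 100, 2000)
    ph <- runif(1, -pi / 2, pi / 2); V <- runif(1, -0.3, -0.05)
    expect_equal(net_dC_from_fit(mk_fit(a, f, al, ph), V),
                 quad_dC(a, f, al, ph, V), tolerance = 1e-8)
  }
  expect_error(net_dC_from_fit(mk_fit(1, 1, 1, 0), 0), "nonzero")
})

test_that("direct integration recovers the capacitance change", {
  # build a current trace as V dC/dt from a known smooth C(t)
  t <- seq(0, 25e-3, by = 1e-5)
  t_on <- 2e-3; t_off <- 12e-3; V <- -0.2
  dC_final <- -0.5e-12
  C <- 100e-12 + ifelse(t >= t_on,
                        dC_final * (1 - exp(-(pmax(t - t_on, 0)) / 1e-3)),
                        0)
  I <- V * c(0, diff(C)) / 1e-5
  tr <- trace_record(t, I * 1e12, y_units = "pA",
                     meta = list(v_hold = V, t_on = t_on, t_off = t_off))
  est <- net_dC_direct(tr)
  expect_equal(est$dC, dC_final, tolerance = 1e-3)
  # adding a constant baseline current leaves the estimate unchanged
  tr2 <- trace_record(t, I * 1e12 + 10, y_units = "pA",
                      meta = list(v_hold = V, t_on = t_on, t_off = t_off))
  expect_lt(abs(net_dC_direct(tr2)$dC - est$dC), 1e-16)
  # no samples before the onset -> no baseline to subtract
  expect_error(net_dC_direct(trace_record(t, I * 1e12, y_units = "pA",
                                          meta = list(v_hold = V,
                                                      t_on = t[1],
                                                      t_off = 10e-3))),
               "baseline")
})

test_that("the two net-dC estimators agree on a pure damped-sine trace", {
  p <- fig1_params()
  tr <- generate_onoff_trace(synthetic_spec(on_params = p, noise_sd = 0,
                                            lowpass_hz = NULL,
                                            t_on = 2e-3, t_off = 14e-3,
                                            duration = 28e-3))
  fit <- fit_damped_sine(tr, "on")
  # the trace is in pA, so the fit-based estimate comes out in pF while
  # the direct integral is in F
  dc_fit_pF <- net_dC_from_fit(fit, -0.2)
  dc_dir_pF <- net_dC_direct(tr)$dC * 1e12
  expect_equal(dc_dir_pF, dc_fit_pF, tolerance = 0.05)
})

test_that("amplitude-capacitance power law fits and normalizes", {
  C <- c(30, 100, 300, 1000) * 1e-12
  pts <- data.frame(C = C, amplitude = 1 * C^1.0)
  law <- fit_amplitude_capacitance_law(pts)
  expect_equal(law$beta, 1, tolerance = 1e-6)
  expect_equal(law$k, 1, tolerance = 1e-6)
  expect_false(law$saturated)
  # two points saturate the two-parameter fit
  law2 <- fit_amplitude_capacitance_law(pts[1:2, ])
  expect_true(law2$saturated)
  expect_error(fit_amplitude_capacitance_law(
    data.frame(C = C, amplitude = c(1, 0, 1, 1))), "nonzero")
  # normalization: identity at the reference, constant on exact law data
  expect_equal(normalize_amplitude(5, 100e-12, 100e-12, law), 5)
  a_n <- normalize_amplitude(pts$amplitude, pts$C, 100e-12, law)
  expect_lt(diff(range(a_n)) / mean(a_n), 1e-6)
})

test_that("model sweep: normalization flattens a >10-fold amplitude range", {
  d <- exp(seq(log(80e-6), log(400e-6), length.out = 7))
  curve <- modal_response_curve(d, gamma = 0.8e-3, P0 = ref_P0,
                                P_US = ref_Pus)
  expect_gt(max(curve$amplitude) / min(curve$amplitude), 10)
  law <- fit_amplitude_capacitance_law(
    data.frame(C = curve$C, amplitude = curve$amplitude))
  # fitted curve interpolates the sweep within 10%
  expect_lt(max(abs(predict_amplitude(law, curve$C) - curve$amplitude) /
                  curve$amplitude), 0.10)
  a_n <- normalize_amplitude(curve$amplitude, curve$C, 100e-12, law)
  expect_lt(diff(range(a_n)) / mean(a_n), 0.15)
})

test_that("capacitance converts to perimeter through the model power law", {
  m <- capacitance_perimeter_model(seq(60e-6, 480e-6, length.out = 6),
                                   gamma = 0.8e-3, P0 = 0,
                                   settings = quick_settings())
  # flat-bilayer limit: C = eps eps0 (pi d^2/4) / L0 inverted by hand
  expect_equal(perimeter_from_capacitance(50e-12, m) * 1e6, 377,
               tolerance = 5e-3)
  # monotone increasing over the fitted range
  Cs <- seq(m$C_range[1], m$C_range[2], length.out = 20)
  expect_true(all(diff(perimeter_from_capacitance(Cs, m)) > 0))
  expect_warning(perimeter_from_capacitance(2 * m$C_range[2], m),
                 "extrapolat")
  # round trip under curvature: known d recovered within 5%
  m2 <- capacitance_perimeter_model(seq(60e-6, 480e-6, length.out = 6),
                                    gamma = 0.8e-3, P0 = ref_P0,
                                    settings = quick_settings())
  eq <- solve_equilibrium(ref_bp(), ref_P0, quick_settings())
  C120 <- compute_capacitance(eq$bp$A0, 4e-9, ref_bp())
  expect_equal(perimeter_from_capacitance(C120, m2), pi * 120e-6,
               tolerance = 0.05)
})
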