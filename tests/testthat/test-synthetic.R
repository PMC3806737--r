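test_that("generator is deterministic per seed", {
  sp1 <- synthetic_spec(on_params = fig1_params(), noise_sd = 50, seed = 5)
  sp2 <- synthetic_spec(on_params = fig1_params(), noise_sd = 50, seed = 5)
  sp3 <- synthetic_spec(on_params = fig1_params(), noise_sd = 50, seed = 6)
  t1 <- generate_onoff_trace(sp1)
  expect_identical(t1$y, generate_onoff_trace(sp2)$y)
  expect_false(identical(t1$y, generate_onoff_trace(sp3)$y))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_onoff_trace(sp1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate generator inputs give flat traces", {
  sp <- synthetic_spec(on_params = list(a = 0, f = 900, alpha = 700,
                                        phi = 0), noise_sd = 0)
  expect_equal(max(abs(generate_onoff_trace(sp)$y)), 0)
})

test_that("generator validates its spec", {
  expect_error(synthetic_spec(on_params = list(a = 1, f = 1, alpha = 1,
                                               phi = 0),
                              t_on = 5e-3, t_off = 1e-3), "t_off")
  expect_error(synthetic_spec(on_params = list(a = 1, f = 1, alpha = 1,
                                               phi = 0),
                              sample_rate = 1.5e4, lowpass_hz = 1e4),
               "twice the low-pass cutoff")
  expect_error(synthetic_spec(on_params = list(a = 1, f = 1)), NULL)
})

test_that("On and Off components sit at the stimulus edges with opposite sign", {
  p <- fig1_params()
  tr <- generate_onoff_trace(synthetic_spec(on_params = p, noise_sd = 0,
                                            lowpass_hz = NULL,
                                            t_on = 2e-3, t_off = 12e-3))
  expect_equal(max(abs(tr$y[tr$t < 2e-3])), 0)
  on_fit <- fit_damped_sine(tr, "on")
  off_fit <- fit_damped_sine(tr, "off")
  expect_gt(on_fit$a, 0)
  expect_lt(off_fit$a, 0)
  expect_equal(off_fit$a, -on_fit$a, tolerance = 2e-3)
})

test_that("post-filter noise SD matches the filter-gain expectation", {
  # white noise of SD sigma filtered by h has SD sigma * sqrt(sum h^2)
  sp0 <- synthetic_spec(on_params = list(a = 0, f = 900, alpha = 700,
                                         phi = 0), noise_sd = 50)
  imp <- lowpass_filter(c(1, rep(0, 4095)), 1e5, 1e4)
  expected_sd <- 50 * sqrt(sum(imp^2))
  sds <- vapply(1:20, function(s) {
    sp <- synthetic_spec(on_params = list(a = 0, f = 900, alpha = 700,
                                          phi = 0), noise_sd = 50,
                         seed = s)
    sd(generate_onoff_trace(sp)$y)
  }, numeric(1))
  expect_equal(mean(sds), expected_sd, tolerance = 0.10)
})

test_that("model-driven traces behave like the modal analysis predicts", {
  preset <- fixture_preset("model")
  prog <- pressure_program(ref_P0, ref_Pus, t_on = 1e-3, t_off = 14e-3)
  amps <- vapply(c(0.075, 0.15, 0.30), function(Pus) {
    tr <- generate_model_trace(preset$bp, preset$med,
                               pressure_program(ref_P0, Pus, t_on = 1e-3,
                                                t_off = 14e-3),
                               preset$cfg, settings = quick_settings(),
                               t_end = 26e-3)
    fit <- fit_damped_sine(tr, "off")
    expect_false(fit$no_oscillation)
    fit$a
  }, numeric(1))
  # amplitude scales linearly with the radiation pressure
  expect_equal(amps[2] / amps[1], 2, tolerance = 0.02)
  expect_equal(amps[3] / amps[2], 2, tolerance = 0.02)
  # flat trace when unforced
  flat <- generate_model_trace(preset$bp, preset$med,
                               pressure_program(ref_P0, 0, t_on = 1e-3,
                                                t_off = 14e-3),
                               preset$cfg, settings = quick_settings(),
                               t_end = 20e-3)
  expect_lt(max(abs(flat$y)), 1e-3)
})

test_that("fixture suite regenerates bit-identically and matches its truth", {
  dir1 <- tempfile("fix1"); dir2 <- tempfile("fix2")
  dir.create(dir1); dir.create(dir2)
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  m1 <- make_fixture_suite(dir1, seed = 11)
  m2 <- make_fixture_suite(dir2, seed = 11)
  for (nm in names(m1$presets)) {
    expect_identical(m1$presets[[nm]]$md5, m2$presets[[nm]]$md5)
  }
  # manifest truth parameters carry the published fit magnitudes
  expect_equal(m1$presets$fig1$truth,
               list(a = 800, f = 900, alpha = 700, phi = -0.21))
  expect_equal(m1$presets$fig4$truth$f, 400)
  expect_equal(m1$presets$fig4$truth$alpha, 340)
  expect_equal(abs(m1$presets$fig4$truth$a), 110)
  expect_equal(m1$presets$`fig7a-small`$truth$f, 2680)
  expect_equal(m1$presets$`fig7a-large`$truth$f, 150)
  expect_equal(m1$presets$`fig7a-small`$c0_f, 30e-12)
  expect_equal(m1$presets$`fig7a-large`$c0_f, 1300e-12)
  # every trace fixture re-fits to its own truth within a few percent
  for (nm in c("fig1", "fig4", "fig7a-small", "fig7a-large")) {
    tr <- read_trace(file.path(dir1, m1$presets[[nm]]$file))
    fit <- fit_damped_sine(tr, "on")
    truth <- m1$presets[[nm]]$truth
    expect_false(fit$no_oscillation)
    expect_equal(fit$f, truth$f, tolerance = 0.05)
    expect_equal(abs(fit$a), abs(truth$a), tolerance = 0.15)
    expect_equal(fit$alpha, truth$alpha, tolerance = 0.25)
  }
})
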