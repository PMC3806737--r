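# One shared reference run: ideal-step On response of the 120-um bilayer
ref_run <- local({
  fld <- NULL
  function() {
    if (is.null(fld))
      fld <<- solve_dynamics(ref_bp(), ref_med(),
                             pressure_program(ref_P0, ref_Pus, t_on = 0),
                             quick_settings(), t_end = 12e-3)
    fld
  }
})

test_that("equilibrium is a fixed point of the dynamics", {
  fld <- solve_dynamics(ref_bp(), ref_med(),
                        pressure_program(ref_P0, P_US = 0, t_on = 0),
                        quick_settings(), t_end = 2e-3)
  u0 <- center_displacement(fld)
  expect_lt(max(abs(u0 - u0[1])), 1e-6 * abs(u0[1]))
  expect_lt(max(abs(fld$v)), 1e-6 * abs(u0[1]) / 1e-3)
})

test_that("the dynamic steady state is the closed-form parabola at P0 + P_US", {
  fld <- ref_run()
  bp <- ref_bp()
  u_end <- fld$u[length(fld$t), ]
  exact <- parabola_profile(fld$x, ref_P0 + ref_Pus, bp$gamma, bp$d)
  expect_lt(max(abs(u_end - exact)), 1e-3 * max(abs(exact)))
})

test_that("displacement change is linear in the radiation pressure", {
  fld1 <- ref_run()
  prog2 <- pressure_program(ref_P0, 2 * ref_Pus, t_on = 0)
  fld2 <- solve_dynamics(ref_bp(), ref_med(), prog2, quick_settings(),
                         t_end = 12e-3)
  du1 <- center_displacement(fld1) - center_displacement(fld1)[1]
  du2 <- center_displacement(fld2) - center_displacement(fld2)[1]
  # doubling P_US doubles both the steady level and the full transient
  steady1 <- mean(tail(du1, 50)); steady2 <- mean(tail(du2, 50))
  expect_equal(steady2 / steady1, 2, tolerance = 1e-2)
  expect_lt(max(abs(du2 - 2 * du1)), 5e-3 * max(abs(du2)))
})

test_that("superposition: response to P1 + P2 equals the sum of responses", {
  base <- center_displacement(ref_run())
  run_at <- function(Pus) {
    fld <- solve_dynamics(ref_bp(), ref_med(),
                          pressure_program(ref_P0, Pus, t_on = 0),
                          quick_settings(), t_end = 12e-3)
    center_displacement(fld)
  }
  du_a <- run_at(0.05) - run_at(0.05)[1]
  du_b <- run_at(0.10) - run_at(0.10)[1]
  du_ab <- base - base[1]              # 0.15 = 0.05 + 0.10
  expect_lt(max(abs(du_ab - (du_a + du_b))), 5e-3 * max(abs(du_ab)))
})

test_that("Off transient mirrors the On transient after steady state", {
  prog <- pressure_program(ref_P0, ref_Pus, t_on = 0, t_off = 12e-3)
  fld <- solve_dynamics(ref_bp(), ref_med(), prog, quick_settings(),
                        t_end = 24e-3)
  u0 <- center_displacement(fld)
  dt <- 1e-5
  n_seg <- 1000L                       # 10 ms of transient
  on_seg <- u0[1:n_seg] - u0[1]
  off_start <- which.min(abs(fld$t - 12e-3))
  off_seg <- u0[off_start + (0:(n_seg - 1))] - u0[off_start - 1]
  expect_lt(max(abs(off_seg + on_seg)), 2e-3 * max(abs(on_seg)))
})

test_that("halving the spatial step leaves centre displacements unchanged", {
  coarse <- center_displacement(ref_run())
  fine <- center_displacement(
    solve_dynamics(ref_bp(), ref_med(),
                   pressure_program(ref_P0, ref_Pus, t_on = 0),
                   quick_settings(n_nodes = 201L), t_end = 12e-3))
  du_c <- coarse - coarse[1]; du_f <- fine - fine[1]
  expect_lt(abs(max(du_c) - max(du_f)) / max(du_f), 5e-3)
  expect_lt(abs(mean(tail(du_c, 50)) - mean(tail(du_f, 50))) /
              mean(tail(du_f, 50)), 5e-3)
})

test_that("modal characteristics follow the dispersion relation", {
  bp <- ref_bp(); med <- ref_med()
  mc <- modal_characteristics(bp, med)
  q <- pi / bp$d
  expect_equal(mc$frequency, sqrt(2 * bp$gamma * q^3 / med$rho) / (2 * pi))
  expect_equal(mc$frequency, 852.77, tolerance = 1e-4)
  # vanishing tension removes the restoring force
  soft <- bilayer_parameters(d = bp$d, gamma = 1e-15)
  expect_lt(modal_characteristics(soft, med)$frequency, 1e-3)
})

test_that("simulated free oscillation matches the modal analysis", {
  # fit the On transient of the simulated current-free displacement:
  # track the centre displacement and fit its oscillation directly
  fld <- ref_run()
  du <- center_displacement(fld) - center_displacement(fld)[1]
  du_ss <- mean(tail(du, 50))
  tr <- trace_record(fld$t, (du - du_ss) * 1e9,
                     meta = list(t_on = 0, t_off = max(fld$t)))
  fit <- fit_damped_sine(tr, window = c(0, 10e-3))
  mc <- modal_characteristics(ref_bp(), ref_med())
  expect_false(fit$no_oscillation)
  expect_equal(fit$f, mc$frequency, tolerance = 0.05)
  expect_equal(fit$alpha, mc$damping, tolerance = 0.15)
})

test_that("solver failures are reported explicitly", {
  expect_error(solve_dynamics(ref_bp(), ref_med(),
                              pressure_program(ref_P0, ref_Pus),
                              quick_settings(), t_end = 0),
               "t_end")
})
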