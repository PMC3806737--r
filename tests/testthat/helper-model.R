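# Reference parameter set: 120-um bilayer, tension 0.8 mN/m, water medium,
# hydrostatic pressure -70 N/m^2, radiation-force pressure 0.15 N/m^2.
ref_bp <- function() bilayer_parameters(d = 120e-6, gamma = 0.8e-3,
                                        L0 = 4e-9, epsilon = 2)
ref_med <- function() medium_properties(rho = 1000, eta = 1e-3, c = 1500)
ref_P0 <- -70
ref_Pus <- 0.15

# coarser grid for routine tests; acceptance uses the full default grid
quick_settings <- function(n_nodes = 101L, dt_out = 1e-5)
  solver_settings(n_nodes = n_nodes, dt_out = dt_out)

# closed-form equilibrium parabola: solution of 2*gamma*u'' = -P
parabola_profile <- function(x, P, gamma, d) (P / (4 * gamma)) * (d^2 / 4 - x^2)

# closed-form lateral area of a paraboloid of revolution (depth h, rim a):
# the independent oracle for the quadrature-based area path
paraboloid_area_oracle <- function(h, a) {
  if (h == 0) return(pi * a^2)
  (pi * a / (6 * h^2)) * ((a^2 + 4 * h^2)^1.5 - a^3)
}

# published damped-sine parameter set for a standard ~170 pF bilayer
fig1_params <- function() list(a = 800, f = 900, alpha = 700, phi = -0.21)
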