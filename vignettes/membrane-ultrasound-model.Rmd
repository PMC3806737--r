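---
title: "Modelling bilayer responses to ultrasonic radiation force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilayer responses to ultrasonic radiation force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsono)
```

## The physical picture

A planar ("black") lipid bilayer is painted across an aperture in a
partition separating two solution compartments. A hydrostatic pressure
difference $P_0$ (negative under the standard recording geometry) bows the
membrane into a curved cap; the restoring pressure comes from the
interfacial tension $\gamma$. When an ultrasound beam hits the preparation,
the steady second-order radiation force adds an effective pressure $P_{US}$
that is switched on and off essentially instantaneously with the stimulus.
The bilayer relaxes toward a new equilibrium curvature through a damped
interfacial oscillation; because elastic area changes conserve hydrophobic
volume, the area change carries a reciprocal thickness change and hence a
capacitance change, which under voltage clamp appears as a capacitive
current $I_C = V\,dC/dt$ shaped like an exponentially decaying sinusoid.

## The displacement model

`solve_dynamics()` integrates the equation of motion for the cross-sectional
displacement $u(x,t)$ of the membrane chord, obtained by reducing the
incompressible Navier–Stokes equation under three assumptions: displacements
are purely axial, the in-plane derivatives are equal by symmetry, and the
interfacial pressure disturbance decays into the bulk as $e^{-qz}$ with
spatial frequency $q = 2\pi/\lambda$, where the clamped rim
($u(\pm d/2,t)=0$) fixes the standing wavelength at $\lambda = 2d$:

$$\rho\,\frac{\partial v}{\partial t}
  = 2\eta\,\frac{\partial^2 v}{\partial x^2}
  + q\left(P + 2\gamma\,\frac{\partial^2 u}{\partial x^2}\right),
  \qquad v = \frac{\partial u}{\partial t},\quad q = \pi/d.$$

Setting the bracket to zero recovers the equilibrium problem
$2\gamma u'' = -P_0$, whose solution is the parabola
$u(x) = (P_0/4\gamma)(d^2/4 - x^2)$; `solve_equilibrium()` solves the
discretized boundary-value problem and the closed form serves as an
independent oracle in the test-suite. Linearising about the flat state
gives, for the fundamental mode, a damped harmonic oscillator with natural
frequency $\sqrt{2\gamma q^3/\rho}/2\pi$ and envelope decay rate
$\eta q^2/\rho$ (`modal_characteristics()`); for the reference 120-µm
bilayer these are 853 Hz and 685 s⁻¹, matching the fitted output of the
full solver to well within the 5 %/15 % cross-check tolerances.

Numerically, the PDE is solved by the method of lines: a uniform grid of
201 nodes (odd, so the centre is a node), second-order central differences,
and the stiff `deSolve::lsoda` integrator with a banded Jacobian on the
interleaved $(u, v)$ state, relative tolerance $10^{-8}$. Ideal-step
stimuli are handled by restarting the integration at the onset and offset
times so the discontinuous forcing is never stepped across; smooth
intensity envelopes (e.g. `quadratic_ramp_envelope()`) are integrated in
one pass. Grid convergence is part of the test-suite: halving the spatial
step changes the peak and steady-state centre displacements by well under
0.5 %.

## Electromechanics

The cross-sectional profile on the half-chord is treated as the radial
profile of an axisymmetric surface, so the area is the
surface-of-revolution integral
$A = \int_0^{d/2} 2\pi r \sqrt{1 + (u')^2}\,dr$, evaluated by adaptive
quadrature (relative tolerance $10^{-9}$) on an `fmm` spline of the
profile — the `fmm` end condition reproduces polynomial profiles exactly,
so the equilibrium parabola integrates to the closed-form
paraboloid-of-revolution area. This radial reading of the area integral is
a deliberate design choice: it reproduces both the ~100 pF resting
capacitance of the reference 120-µm bilayer and its 0.16 % steady-state
area change, whereas a planar arc-length reading does not.

Elastic deformations conserve hydrophobic volume, so
$L = L_0 A_0/A$ (`compute_thickness()`), and the parallel-plate law
$C = \varepsilon\varepsilon_0 A/L$ then implies the quadratic relation
$C/C_0 = (A/A_0)^2$, asserted as an invariant on simulated series. The
defaults $L_0 = 4$ nm (solvent-containing bilayers) and $\varepsilon = 2$
are constants of record and user-overridable. Voltage-clamp currents use
centred differences for $dC/dt$ (one-sided at the ends); current-clamp
voltages are returned both exactly ($V_0 C_0/C$, constant charge) and in
the small-change linearisation, which agree within 1 % whenever
$|\Delta C/C_0| < 1\,\%$.

## Waveform analysis

`fit_damped_sine()` fits $a\,e^{-\alpha t}\sin(2\pi f t + \varphi)$ to an
On or Off transient by Levenberg–Marquardt least squares. Initialisation is
deterministic: $f$ from the dominant FFT peak, $\alpha$ from a log-linear
fit to the analytic-signal envelope, and $(a, \varphi)$ from the linear
subproblem at that $(f, \alpha)$. The fit window runs from the stimulus
edge to where the envelope falls below twice the pre-stimulus baseline SD
(minimum two periods). Because $(a,\varphi)$ and $(-a,\varphi+\pi)$
describe the same curve, results are canonicalised to
$\varphi \in (-\pi/2, \pi/2]$ with the sign carried by the amplitude, the
convention of published fits; Off amplitudes are therefore reported signed.
A transient whose amplitude is indistinguishable from noise (below twice
the baseline SD) is flagged `no_oscillation` rather than fitted — the
behaviour of strongly damped membranes such as those formed from
cholesterol, for which only a brief spike and no fittable oscillation is
seen. Only the primary oscillatory component is fitted; the residual RMS is
reported so secondary components show up as misfit.

The net capacitance change is estimated two ways, and the estimators
cross-check each other: in closed form from the fitted transient,

$$\Delta C = \frac{a}{V}\,
  \frac{\omega\cos\varphi + \alpha\sin\varphi}{\alpha^2 + \omega^2},
  \qquad \omega = 2\pi f,$$

(the improper integral of the fitted curve divided by the holding
potential), and directly, by baseline-subtracting the current, integrating
cumulatively, dividing by $V$ and averaging over the final millisecond of
the stimulus. The direct estimator will faithfully report any slow drift
component present in a trace (the generator can add one via
`slow_component`); the fit-based estimator sees only the oscillatory
transient — this is why the fit-based route is the reference for the fast
elastic component.

Amplitude normalisation across bilayers of different size uses the power
law $F_C(C) = kC^\beta$ fitted in log space
(`fit_amplitude_capacitance_law()`), applied as $a_n = a F_C(C_0)/F_C(C)$,
and `capacitance_perimeter_model()` converts measured capacitance to an
estimated perimeter through the same kind of power-law fit to the
model-generated capacitance–perimeter table. The power law is an
approximation to the model curve: over roughly a 16-fold amplitude range
(diameters 80–400 µm) it interpolates the sweep to better than 10 % and
flattens the normalised amplitudes to a ~13 % spread; over much wider
ranges its quality degrades, so the fitted capacitance range is recorded
and extrapolation warns.

## Linear-system prediction

Because the PDE and the (small-signal) electromechanics are linear in the
forcing, the On response to an ideal-step stimulus is the system's step
response. `step_to_impulse()` differences it with one-sided first
differences — chosen over centred differences so that a discrete Heaviside
step maps to a single-sample impulse and the cumulative sum reproduces the
step exactly — and `predict_response()` convolves the impulse response with
any intensity envelope in $[0,1]$. The test-suite closes the loop
quantitatively: convolution predictions match direct PDE simulations with
quadratically ramped forcing to better than 2 % RMS for 0.5-, 2- and 5-ms
ramps. That cross-check is run with 5-µs output sampling: at the standard
100-kHz rate the first-order differencing error alone contributes ~2 % RMS
for the fastest ramp and would mask the linearity being tested.

## Synthetic data

`generate_onoff_trace()` emulates a voltage-clamp recording: a damped
sinusoid from the onset, an opposite-polarity but otherwise identical one
from the offset, seeded Gaussian baseline noise, and optionally a causal
low-pass filter (default realisation a 4th-order Bessel, the
maximally-flat-delay type typical of patch-clamp hardware, discretised by
the bilinear transform with cutoff prewarping). Defaults follow the
recording conditions: 100 kHz sampling, 10 kHz cutoff. Two things the
generator deliberately does *not* emulate: correlated (1/f or line) noise,
and amplifier/access-resistance dynamics. Note also that hardware-style
filtering is *not* neutral for the fastest transients — for the 2.68-kHz,
1370 s⁻¹ preset the filter alone biases the fitted damping by ~20 % — so
the canonical fixture suite (`make_fixture_suite()`) stores unfiltered
traces whose manifest truth parameters are exact, with noise SD 20 pA (the
baseline-noise scale of trial-averaged records), and filtering is applied
only on request. Passing round-trip tests on these fixtures therefore
demonstrates estimator correctness against known truth, not robustness to
every distortion of real recordings.

`generate_model_trace()` composes the PDE, electromechanics and noise into
end-to-end simulated recordings, and `calibrate_parameters()` recovers
$\gamma$ (optionally $P_0$, $P_{US}$) from observed
(capacitance, amplitude, frequency, damping) tuples. The calibration
forward map is the closed-form fundamental-mode approximation
(`modal_response_curve()`), not the full PDE: an optimisation inside a
Monte-Carlo loop needs thousands of model evaluations, and the modal map
agrees with the PDE observables to a few percent while costing
microseconds. The full solver remains the production path everywhere else
and cross-checks the modal map in the tests.

## Problem sizes and numerical choices of record

* Spatial grid 201 nodes (tests mostly 101), `rtol` $10^{-8}$,
  `atol` $10^{-14}$, output at 100 kHz.
* Reference simulations cover 12–15 ms of On response — about ten damping
  time constants for the 120-µm bilayer, so plateau averages over the final
  millisecond are settled to ~$3\times10^{-4}$ relative.
* The Monte-Carlo coverage study uses 100 seeded replicates at 50 pA noise
  (unfiltered, so generator truth is exact); the estimator-agreement study
  draws phases from the $(-0.7, 0.7)$ rad band spanned by observed fits —
  near $|\varphi| \to \pi/2$ the net-$\Delta C$ integral approaches a sign
  change where no relative tolerance is meaningful.
* All stochastic operations take explicit seeds (default 0) and restore the
  caller's RNG state.

## A worked example

```{r, eval = FALSE}
run <- run_pipeline()        # reference 120-um configuration, 10-ms pulse
run                          # resting C 102.5 pF, Off fit ~844 Hz, 687 1/s
u0 <- center_displacement(run$field)
# steady-state displacement during the stimulus (plateau before offset)
during <- run$field$t > 11e-3 & run$field$t < 12e-3
(mean(u0[during]) - u0[1]) * 1e6      # 0.169 um
net_dC_from_fit(run$fit_on, -0.2)     # -0.32 pF net capacitance change
```

## Known limitations

* No interfacial (surface) viscosity term: membranes dominated by
  cholesterol, with interfacial viscosities orders of magnitude above
  phospholipid bilayers, are outside the model. The analysis side handles
  them only through the `no_oscillation` flag.
* No coupling to the solution/air interface, acoustic streaming, or
  viscoelastic rim: the rim is an ideal clamp and the radiation force is an
  imposed pressure, so geometry-specific sources of the force are inputs,
  not outputs.
* Tension is constant during deformation; the constant-volume elastic mode
  is the only area-change mechanism modelled, so slow lipid exchange with
  the torus appears only as an optional drift term in the generator.
* The acoustic relations are plane-wave formulas; no beam profiles,
  focusing or transducer-efficiency corrections.
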