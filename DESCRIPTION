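Package: memsono
Title: Membrane Bilayer Dynamics and Electrophysiology Under Ultrasonic
    Radiation Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the mechanical and electrical response of planar lipid
    bilayers (black lipid membranes) to ultrasonic radiation force.
    Solves an interfacial capillary-wave partial differential equation for
    the bilayer displacement by the method of lines, maps displacement
    profiles to membrane area, thickness, capacitance, capacitive current
    and current-clamp voltage under the constant-volume elastic deformation
    model, and analyses voltage-clamp current traces: damped-sinusoid
    fitting, net capacitance-change estimation by two independent
    estimators, capacitance normalization of response amplitudes, and
    perimeter estimation from capacitance. Also provides acoustic
    intensity/pressure bookkeeping for plane waves, a linear-system
    step-response/impulse-response/convolution predictor for modulated
    ultrasound stimuli, and a seeded synthetic-trace generator emulating
    voltage-clamp recordings sampled at 100 kHz.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
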