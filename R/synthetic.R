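#' Specification of a synthetic On/Off voltage-clamp trace
#'
#' Describes a synthetic capacitive-current recording: a damped sinusoid at
#' stimulus onset, an opposite-polarity but otherwise identical damped
#' sinusoid at offset, Gaussian baseline noise, and an optional low-pass
#' filter emulating the recording hardware (default 4th-order Bessel at
#' 10 kHz; the sampling rate defaults to 100 kHz).
#'
#' @param on_params Named list `a` (signal units), `f` (Hz), `alpha` (1/s),
#'   `phi` (rad) for the On transient.
#' @param off_params Same for the Off transient; default is the On set with
#'   the amplitude sign flipped ("opposite in polarity but otherwise
#'   identical").
#' @param t_on,t_off Stimulus onset/offset times (s).
#' @param duration Record length (s).
#' @param sample_rate Sampling rate (Hz), default 1e5. Must exceed twice
#'   the low-pass cutoff.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param lowpass_hz Low-pass cutoff (Hz), or `NULL` for no filtering.
#' @param filter_order,filter_type Filter realisation; `"bessel"` (default)
#'   or `"butterworth"`.
#' @param slow_component Optional list `amplitude`, `tau` (s) adding a slow
#'   exponential drift `amplitude * (1 - exp(-(t - t_on)/tau))` during the
#'   stimulus (and decaying back after offset) — the slow capacitance-drift
#'   component sometimes present in recordings. Default `NULL` (off).
#' @param y_units Signal units, default `"pA"`.
#' @param v_hold,c0 Metadata: holding potential (V), baseline capacitance
#'   (F).
#' @param seed Integer seed, default 0.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(on_params, off_params = NULL,
                           t_on = 2e-3, t_off = 12e-3, duration = 25e-3,
                           sample_rate = 1e5, noise_sd = 0,
                           lowpass_hz = 1e4, filter_order = 4L,
                           filter_type = c("bessel", "butterworth"),
                           slow_component = NULL, y_units = "pA",
                           v_hold = -0.2, c0 = NULL, seed = 0L) {
  filter_type <- match.arg(filter_type)
  req <- c("a", "f", "alpha", "phi")
  stopifnot(is.list(on_params), all(req %in% names(on_params)))
  if (is.null(off_params)) {
    off_params <- on_params
    off_params$a <- -on_params$a
  }
  stopifnot(is.list(off_params), all(req %in% names(off_params)))
  if (!(t_off > t_on)) stop("'t_off' must exceed 't_on'")
  if (duration <= 0 || sample_rate <= 0) stop("durations must be positive")
  if (!is.null(lowpass_hz) && sample_rate <= 2 * lowpass_hz)
    stop("sample_rate must exceed twice the low-pass cutoff")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(on_params = on_params, off_params = off_params,
                 t_on = t_on, t_off = t_off, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 lowpass_hz = lowpass_hz, filter_order = filter_order,
                 filter_type = filter_type,
                 slow_component = slow_component, y_units = y_units,
                 v_hold = v_hold, c0 = c0, seed = as.integer(seed)),
            class = "synthetic_spec")
}

damped_sine_eval <- function(t, p) {
  ifelse(t >= 0,
         p$a * exp(-p$alpha * pmax(t, 0)) * sin(2 * pi * p$f * pmax(t, 0) +
                                                  p$phi),
         0)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Generate a synthetic On/Off capacitive-current trace
#'
#' Deterministic per seed: two calls with the same spec are bit-identical.
#'
#' @param spec A [synthetic_spec()].
#' @return A [trace_record()]; `meta$truth` carries the generating
#'   parameters.
#' @examples
#' sp <- synthetic_spec(on_params = list(a = 800, f = 900, alpha = 700,
#'                                       phi = -0.21), noise_sd = 50)
#' tr <- generate_onoff_trace(sp)
#' @export
generate_onoff_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  y <- damped_sine_eval(t - spec$t_on, spec$on_params) +
    damped_sine_eval(t - spec$t_off, spec$off_params)
  if (!is.null(spec$slow_component)) {
    sc <- spec$slow_component
    during <- t >= spec$t_on & t < spec$t_off
    after <- t >= spec$t_off
    y[during] <- y[during] +
      sc$amplitude * (1 - exp(-(t[during] - spec$t_on) / sc$tau))
    lvl <- sc$amplitude * (1 - exp(-(spec$t_off - spec$t_on) / sc$tau))
    y[after] <- y[after] + lvl * exp(-(t[after] - spec$t_off) / sc$tau)
  }
  if (spec$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(spec$seed)
    y <- y + stats::rnorm(length(y), sd = spec$noise_sd)
  }
  if (!is.null(spec$lowpass_hz))
    y <- lowpass_filter(y, spec$sample_rate, spec$lowpass_hz,
                        order = spec$filter_order, type = spec$filter_type)
  trace_record(t, y, y_units = spec$y_units,
               meta = list(t_on = spec$t_on, t_off = spec$t_off,
                           v_hold = spec$v_hold, c0 = spec$c0,
                           truth = list(on = spec$on_params,
                                        off = spec$off_params,
                                        noise_sd = spec$noise_sd,
                                        seed = spec$seed)))
}

#' Causal low-pass filter emulating recording hardware
#'
#' Default is a 4th-order Bessel filter (maximally flat group delay, the
#' realisation typical of patch-clamp hardware), discretised by the
#' bilinear transform with cutoff prewarping; a Butterworth realisation is
#' also available. Applied in one causal pass, as hardware would.
#'
#' @param y Signal.
#' @param fs Sampling rate (Hz).
#' @param cutoff -3 dB cutoff (Hz), below `fs/2`.
#' @param order Filter order: 2 or 4 for `"bessel"`, any order supported by
#'   `signal::butter` for `"butterworth"`.
#' @param type `"bessel"` or `"butterworth"`.
#' @return Filtered signal, same length.
#' @export
lowpass_filter <- function(y, fs, cutoff, order = 4L,
                           type = c("bessel", "butterworth")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  if (type == "butterworth") {
    bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
    return(as.numeric(signal::filter(bf, y)))
  }
  ba <- bessel_lowpass_coef(order, fs, cutoff)
  as.numeric(signal::filter(ba$b, ba$a, y))
}

# pole locations of low-order Bessel prototypes, -3 dB at 1 rad/s
bessel_prototype_poles <- function(order) {
  switch(as.character(order),
         "2" = complex(real = -1.1016013306,
                       imaginary = c(0.6360098248, -0.6360098248)),
         "4" = c(complex(real = -0.9952087644,
                         imaginary = c(1.2571057395, -1.2571057395)),
                 complex(real = -1.3700678306,
                         imaginary = c(0.4102497175, -0.4102497175))),
         stop("Bessel realisation supports orders 2 and 4"))
}

bessel_lowpass_coef <- function(order, fs, cutoff) {
  p <- bessel_prototype_poles(order)
  # bilinear transform with prewarped analog cutoff (T = 2 convention)
  W <- tan(pi * cutoff / fs)
  sp <- p * W
  sg <- Re(prod(-sp))
  zp <- (1 + sp) / (1 - sp)
  zg <- Re(sg / prod(1 - sp))
  zz <- rep(-1 + 0i, order)      # zeros at Nyquist
  b <- Re(zg * poly_from_roots(zz))
  a <- Re(poly_from_roots(zp))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' End-to-end simulated voltage-clamp trace from the mechanical model
#'
#' Composes [solve_dynamics()] and [electrical_series()] into a sampled
#' current trace with optional seeded Gaussian noise; metadata records the
#' generating configuration.
#'
#' @param bp A [bilayer_parameters()].
#' @param med A [medium_properties()].
#' @param prog A [pressure_program()].
#' @param cfg A [voltage_clamp_config()] in vclamp mode.
#' @param noise_sd Noise SD in pA, default 0.
#' @param seed Seed for the noise, default 0.
#' @param settings [solver_settings()].
#' @param t_end Simulation end time (s), forwarded to [solve_dynamics()].
#' @return A [trace_record()] in pA; `meta$series` holds the full
#'   [electrical_series()].
#' @export
generate_model_trace <- function(bp, med, prog, cfg, noise_sd = 0,
                                 seed = 0L, settings = solver_settings(),
                                 t_end = NULL) {
  stopifnot(inherits(cfg, "voltage_clamp_config"), cfg$mode == "vclamp")
  field <- solve_dynamics(bp, med, prog, settings, t_end = t_end)
  es <- electrical_series(field, bp, cfg)
  y <- es$I_C * 1e12
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  trace_record(es$t, y, y_units = "pA",
               meta = list(t_on = prog$t_on,
                           t_off = min(prog$t_off, max(es$t)),
                           v_hold = cfg$V0, c0 = attr(es, "C0"),
                           series = es))
}

#' Named presets for synthetic fixtures
#'
#' Damped-sine parameter sets representative of published voltage-clamp
#' recordings across the capacitance range (a standard ~170 pF
#' phospholipid bilayer; a solvent-free squalene bilayer; low- and
#' high-capacitance extremes), plus the reference model configuration
#' (120-um bilayer, ~100 pF).
#'
#' @param name One of `"fig1"`, `"fig4"`, `"fig7a-small"`, `"fig7a-large"`,
#'   `"model"`.
#' @param noise_sd Noise SD (pA) for the damped-sine presets; default 20,
#'   the baseline-noise scale of trial-averaged recordings.
#' @param lowpass_hz Low-pass cutoff for the generated traces; default
#'   `NULL` (unfiltered) so that the generator parameters are exact truth —
#'   hardware-style filtering visibly distorts the fastest transients and
#'   can be enabled explicitly.
#' @param seed Seed.
#' @return A [synthetic_spec()] for the trace presets, or a named list of
#'   model objects for `"model"`.
#' @export
fixture_preset <- function(name = c("fig1", "fig4", "fig7a-small",
                                    "fig7a-large", "model"),
                           noise_sd = 20, lowpass_hz = NULL, seed = 0L) {
  name <- match.arg(name)
  if (name == "model") {
    return(list(
      bp = bilayer_parameters(d = 120e-6, gamma = 0.8e-3, L0 = 4e-9,
                              epsilon = 2),
      med = medium_properties(rho = 1000, eta = 1e-3, c = 1500),
      prog = pressure_program(P0 = -70, P_US = 0.15, t_on = 2e-3,
                              t_off = 12e-3),
      cfg = voltage_clamp_config(V0 = -0.2)))
  }
  par <- switch(name,
    "fig1" = list(on = list(a = 800, f = 900, alpha = 700, phi = -0.21),
                  c0 = 170e-12),
    "fig4" = list(on = list(a = 110, f = 400, alpha = 340, phi = 0.19),
                  c0 = 500e-12),
    "fig7a-small" = list(on = list(a = 290, f = 2680, alpha = 1370,
                                   phi = -0.68), c0 = 30e-12),
    "fig7a-large" = list(on = list(a = 1570, f = 150, alpha = 270,
                                   phi = 0.06), c0 = 1300e-12))
  # presets quote the published Off-fit magnitudes; On transient carries
  # positive polarity at negative holding potential, Off the opposite
  dur <- if (par$on$f < 300) 80e-3 else 25e-3
  t_off <- if (par$on$f < 300) 40e-3 else 12e-3
  synthetic_spec(on_params = par$on, t_on = 2e-3, t_off = t_off,
                 duration = dur, noise_sd = noise_sd,
                 lowpass_hz = lowpass_hz, c0 = par$c0, seed = seed)
}

#' Write a reproducible suite of synthetic fixture files
#'
#' Writes each trace preset (see [fixture_preset()]) as a delimited-text
#' trace file plus a JSON manifest listing seeds, generator truth
#' parameters and file digests; the suite regenerates bit-identically from
#' the manifest inputs. The reference model configuration is written as a
#' JSON config.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Base seed; preset `i` uses `seed + i - 1`.
#' @param noise_sd Noise SD (pA) for the trace presets.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(out_dir, seed = 0L, noise_sd = 20) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("'out_dir' is not writable")
  presets <- c("fig1", "fig4", "fig7a-small", "fig7a-large")
  entries <- list()
  for (i in seq_along(presets)) {
    nm <- presets[i]
    sp <- fixture_preset(nm, noise_sd = noise_sd, seed = seed + i - 1L)
    tr <- generate_onoff_trace(sp)
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_trace(tr, path)
    entries[[nm]] <- list(file = basename(path), seed = sp$seed,
                          noise_sd = noise_sd,
                          truth = sp$on_params,
                          c0_f = sp$c0, t_on_s = sp$t_on,
                          t_off_s = sp$t_off,
                          md5 = unname(tools::md5sum(path)))
  }
  model <- fixture_preset("model")
  cfgpath <- file.path(out_dir, "model-config.json")
  write_config(list(rho = model$med$rho, eta = model$med$eta,
                    c = model$med$c, gamma = model$bp$gamma,
                    P0 = model$prog$P0, P_US = model$prog$P_US,
                    d = model$bp$d, L0 = model$bp$L0,
                    epsilon = model$bp$epsilon, t_on = model$prog$t_on,
                    t_off = model$prog$t_off, V0 = model$cfg$V0,
                    n_nodes = 201, rtol = 1e-8, dt_out = 1e-5, seed = seed),
               cfgpath)
  entries[["model"]] <- list(file = basename(cfgpath),
                             md5 = unname(tools::md5sum(cfgpath)))
  manifest <- list(version = as.character(utils::packageVersion("memsono")),
                   base_seed = seed, presets = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
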