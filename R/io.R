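#' Write a trace to delimited text
#'
#' The trace dialect is two tab-separated columns (`time_s`, `value`) with
#' a commented header of `key=value` metadata lines; the units line is
#' mandatory. [read_trace()] reads the same dialect; a write/read round
#' trip is lossless to better than 1e-12 relative.
#'
#' @param trace A [trace_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# memsono trace v1", con)
  writeLines(sprintf("# units=%s", trace$y_units), con)
  writeLines(sprintf("# sample_rate_hz=%.17g", 1 / mean(diff(trace$t))),
             con)
  meta <- trace$meta
  for (k in c("t_on", "t_off", "v_hold", "c0", "n_avg")) {
    if (!is.null(meta[[k]]) && is.numeric(meta[[k]]) &&
        is.finite(meta[[k]]))
      writeLines(sprintf("# %s=%.17g", k, meta[[k]]), con)
  }
  writeLines("time_s\tvalue", con)
  writeLines(sprintf("%.17g\t%.17g", trace$t, trace$y), con)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' @param path File in the dialect written by [write_trace()]. CRLF and LF
#'   line endings are both accepted.
#' @return A [trace_record()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_comment <- grepl("^#", lines)
  header <- lines[is_comment]
  meta <- list()
  for (ln in header) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$units))
    stop("malformed trace header: missing 'units' line (line ",
         which(!is_comment)[1] - 1L, ")")
  body <- lines[!is_comment]
  body <- body[nzchar(body)]
  if (length(body) < 2L || !grepl("^time_s", body[1]))
    stop("malformed trace: expected 'time_s\\tvalue' column header at ",
         "line ", sum(is_comment) + 1L)
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = c("time_s", "value"),
                           colClasses = "numeric")
  dt <- diff(dat$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    bad <- which(dt <= 0 | abs(dt - mean(dt)) > 1e-6 * mean(dt))[1]
    stop("non-uniform time base at data line ", bad + 1L)
  }
  num_or_null <- function(k)
    if (is.null(meta[[k]])) NULL else as.numeric(meta[[k]])
  trace_record(dat$time_s, dat$value, y_units = meta$units,
               meta = list(t_on = num_or_null("t_on"),
                           t_off = num_or_null("t_off"),
                           v_hold = num_or_null("v_hold"),
                           c0 = num_or_null("c0"),
                           n_avg = num_or_null("n_avg")))
}

config_keys <- function() {
  c("rho", "eta", "c", "gamma", "P0", "P_US", "d", "L0", "epsilon",
    "t_on", "t_off", "V0", "n_nodes", "rtol", "dt_out", "seed")
}

#' Default model configuration
#'
#' The constants of record: water at room temperature (`rho` 1000 kg/m^3,
#' `eta` 1 mPa s, `c` 1500 m/s), a 120-um bilayer with tension 0.8 mN/m,
#' hydrophobic thickness 4 nm and dielectric constant 2, hydrostatic
#' pressure -70 N/m^2, radiation-force pressure 0.15 N/m^2, a 10-ms
#' stimulus, -200 mV holding potential and the default solver grid. All
#' values SI.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(rho = 1000, eta = 1e-3, c = 1500, gamma = 0.8e-3, P0 = -70,
       P_US = 0.15, d = 120e-6, L0 = 4e-9, epsilon = 2,
       t_on = 2e-3, t_off = 12e-3, V0 = -0.2,
       n_nodes = 201L, rtol = 1e-8, dt_out = 1e-5, seed = 0L)
}

#' Read a model configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()]
#' unless `strict = TRUE`, in which case every key must be present. All
#' physical values are SI.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @param strict Require all keys to be present.
#' @return Named configuration list.
#' @export
read_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(config_keys(), names(cfg))
  if (strict && length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  out <- utils::modifyList(default_config(), cfg)
  numeric_keys <- setdiff(config_keys(), c("n_nodes", "seed"))
  for (k in numeric_keys) {
    if (!is.numeric(out[[k]]) || length(out[[k]]) != 1L ||
        !is.finite(out[[k]]))
      stop("config key '", k, "' must be a single finite number")
  }
  out$n_nodes <- as.integer(out$n_nodes)
  out$seed <- as.integer(out$seed)
  out
}

#' Write a configuration as JSON
#'
#' @param cfg Named list of configuration values.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full simulation and analysis pipeline
#'
#' Orchestrates the reference workflow: equilibrium profile at `P0`,
#' dynamic solve over the stimulus window, electromechanical series,
#' noiseless capacitive-current trace, and damped-sine fits of the On and
#' Off transients. A run manifest records the configuration snapshot,
#' package version, seed, digests and timestamps, so every number in the
#' bundle is traceable to a configuration and seed.
#'
#' @param config Named list as from [read_config()] / [default_config()],
#'   or a path to a config file.
#' @param t_end Simulation end time (s); default `t_off + 15e-3`.
#' @param fit_windows Fit the On/Off transients (set `FALSE` to skip, e.g.
#'   for pure mechanics runs).
#' @return Object of class `memsono_pipeline`: `config`, `equilibrium`,
#'   `field`, `series`, `trace`, `fit_on`, `fit_off`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), t_end = NULL,
                         fit_windows = TRUE) {
  if (is.character(config)) config <- read_config(config)
  missing <- setdiff(config_keys(), names(config))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  bp <- bilayer_parameters(d = config$d, gamma = config$gamma,
                           L0 = config$L0, epsilon = config$epsilon)
  med <- medium_properties(rho = config$rho, eta = config$eta,
                           c = config$c)
  prog <- pressure_program(P0 = config$P0, P_US = config$P_US,
                           t_on = config$t_on, t_off = config$t_off)
  settings <- solver_settings(n_nodes = config$n_nodes,
                              rtol = config$rtol, dt_out = config$dt_out)
  cfg <- voltage_clamp_config(V0 = config$V0)
  started <- Sys.time()
  eqm <- solve_equilibrium(bp, config$P0, settings)
  field <- solve_dynamics(eqm$bp, med, prog, settings, t_end = t_end)
  series <- electrical_series(field, eqm$bp, cfg)
  trace <- trace_record(series$t, series$I_C * 1e12, y_units = "pA",
                        meta = list(t_on = prog$t_on,
                                    t_off = min(prog$t_off,
                                                max(series$t)),
                                    v_hold = cfg$V0,
                                    c0 = attr(series, "C0")))
  fit_on <- fit_off <- NULL
  if (fit_windows) {
    fit_on <- fit_damped_sine(trace, "on")
    fit_off <- fit_damped_sine(trace, "off")
  }
  manifest <- list(
    tool = "memsono",
    version = as.character(utils::packageVersion("memsono")),
    seed = config$seed,
    config = config,
    config_md5 = md5_of_object(config),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(list(config = config, equilibrium = eqm, field = field,
                 series = series, trace = trace, fit_on = fit_on,
                 fit_off = fit_off, manifest = manifest),
            class = "memsono_pipeline")
}

#' @export
print.memsono_pipeline <- function(x, ...) {
  cat("memsono pipeline run\n")
  cat(sprintf("  config md5 %s, seed %d\n", x$manifest$config_md5,
              x$manifest$seed))
  u0 <- center_displacement(x$field)
  cat(sprintf("  centre displacement: rest %.4g um, final %.4g um\n",
              u0[1] * 1e6, u0[length(u0)] * 1e6))
  cat(sprintf("  resting capacitance: %.4g pF\n",
              attr(x$series, "C0") * 1e12))
  if (!is.null(x$fit_off) && !x$fit_off$no_oscillation)
    cat(sprintf("  Off fit: a %.4g pA, f %.4g Hz, alpha %.4g 1/s\n",
                x$fit_off$a, x$fit_off$f, x$fit_off$alpha))
  invisible(x)
}

#' Write a pipeline results bundle to a directory
#'
#' Emits the electrical series and current trace as delimited text, the
#' displacement field in long format (`t`, `x`, `u`, `v`), and the run
#' manifest as JSON with output-file digests added.
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @param field_stride Keep every `field_stride`-th time sample of the
#'   displacement field (default 10) to bound file size.
#' @return Invisibly, the manifest.
#' @export
write_results_bundle <- function(run, out_dir, field_stride = 10L) {
  stopifnot(inherits(run, "memsono_pipeline"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  es_path <- file.path(out_dir, "electrical_series.tsv")
  utils::write.table(format(run$series, digits = 12), es_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr_path <- file.path(out_dir, "current_trace.tsv")
  write_trace(run$trace, tr_path)
  idx <- seq(1L, length(run$field$t), by = field_stride)
  long <- data.frame(
    t = rep(run$field$t[idx], each = length(run$field$x)),
    x = rep(run$field$x, times = length(idx)),
    u = as.vector(t(run$field$u[idx, , drop = FALSE])),
    v = as.vector(t(run$field$v[idx, , drop = FALSE])))
  fl_path <- file.path(out_dir, "displacement_field.tsv")
  utils::write.table(format(long, digits = 12), fl_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- run$manifest
  manifest$outputs <- lapply(c(electrical_series = es_path,
                               current_trace = tr_path,
                               displacement_field = fl_path),
                             function(p) list(file = basename(p),
                                              md5 = unname(
                                                tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
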