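#' Run an analysis stage from a configuration
#'
#' Reproducible orchestration of the package's stages from a single
#' configuration document (a YAML file path or an equivalent named list).
#' Every run writes a JSON summary embedding the package version, a hash of
#' the canonicalised configuration, and the seed, so identical
#' configurations produce byte-identical summaries.
#'
#' Stages and their configuration blocks:
#' \describe{
#'   \item{`generate`}{`type` = `"wave"`, `"transport"` or `"calibration"`
#'     plus the matching scenario fields; writes a trace table or
#'     calibration CSV to `output`.}
#'   \item{`calibrate`}{`input` calibration CSV; fits the log-linear curve,
#'     writes it as JSON next to the summary.}
#'   \item{`quantify`}{`input` trace table + `curve` JSON; inverts sensor
#'     response to concentration, writes a trace table.}
#'   \item{`fit-flow`}{`input` trace table + `r`, `source_mM`,
#'     `positions_cm`, `lateral_tau_s`; fits the xylem flow rate.}
#'   \item{`kinetics`}{`input` trace table + `stimulus_time`; extracts wave
#'     features per channel, writes a feature table.}
#'   \item{`decay`}{`x`, `y` vectors (or `input` CSV with those columns);
#'     exponential distance-decay fit.}
#'   \item{`simulate-mechanism`}{lattice/event fields; writes the simulated
#'     sensor traces as a trace table.}
#' }
#'
#' @param config path to a YAML config or a named list. Must contain
#'   `stage`; `seed` defaults to 1.
#' @param out_dir output directory (default: directory of the config file,
#'   or the working directory).
#' @return The summary list, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (is.null(out_dir)) out_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(out_dir)) out_dir <- "."
  if (!is.list(config) || is.null(config$stage)) {
    stop("config must be a named list (or YAML file) with at least `stage`; ",
         "stages: generate, calibrate, quantify, fit-flow, kinetics, decay, ",
         "simulate-mechanism", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stage <- config$stage
  results <- switch(
    stage,
    "generate" = stage_generate(config, out_dir, seed),
    "calibrate" = stage_calibrate(config, out_dir),
    "quantify" = stage_quantify(config, out_dir),
    "fit-flow" = stage_fit_flow(config, out_dir),
    "kinetics" = stage_kinetics(config, out_dir),
    "decay" = stage_decay(config),
    "simulate-mechanism" = stage_simulate(config, out_dir),
    stop(sprintf("unknown stage `%s`", stage), call. = FALSE)
  )
  summary <- list(stage = stage,
                  package_version = as.character(utils::packageVersion("sapwave")),
                  config_hash = config_hash(config),
                  seed = seed,
                  results = results)
  out <- file.path(out_dir, sprintf("summary_%s.json", gsub("-", "_", stage)))
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(summary)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  canon <- config[order(names(config))]
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage_generate <- function(config, out_dir, seed) {
  type <- config$type %||% "wave"
  output <- file.path(out_dir, config$output %||% sprintf("%s_traces.csv", type))
  if (type == "calibration") {
    d <- gen_calibration_dataset(
      sensitivity = config$sensitivity %||% 116.7,
      intercept = config$intercept %||% 0,
      reference = config$reference %||% min(config$concentrations %||% 0.75),
      concentrations = config$concentrations %||% 75 * 10^seq(-2, 0, length.out = 6),
      noise_sd = config$noise_sd %||% 0,
      noise_frac = config$noise_frac %||% 0,
      seed = seed)
    utils::write.csv(d, output, row.names = FALSE, quote = FALSE)
    return(list(output = basename(output), n = nrow(d)))
  }
  if (type == "transport") {
    sc <- transport_scenario(
      u = config$u %||% 0.35, r = config$r %||% 0.012,
      source_mM = config$source_mM %||% 75,
      positions_cm = config$positions_cm %||% c(1, 2),
      lateral_tau = config$lateral_tau_s %||% 60,
      noise_frac = config$noise_frac %||% 0, seed = seed)
    t_grid <- seq(0, config$t_end %||% 1500, by = 1 / (config$fs %||% 0.2))
    traces <- gen_transport_traces(sc, t_grid)
    names(traces) <- sprintf("x%gcm", sc$geometry$positions_cm)
    write_trace_table(traces, output)
    return(list(output = basename(output), n_traces = length(traces)))
  }
  sc <- wave_scenario(
    stimulus_time = config$stimulus_time %||% 30,
    stimulus_position = config$stimulus_position %||% 0,
    sensor_positions = config$sensor_positions %||% c(1, 2),
    velocity_down = config$velocity_down %||% 0.39,
    velocity_counter = config$velocity_counter %||% 0.16,
    amplitude0 = config$amplitude0 %||% 100,
    amplitude_decay = config$amplitude_decay %||% 1.53,
    risetime_floor = config$risetime_floor %||% 9.9,
    noise_sd = config$noise_sd %||% 0,
    fs = config$fs %||% 10,
    kind = config$kind %||% "h2o2",
    seed = seed)
  traces <- gen_wave_traces(sc)
  names(traces) <- sprintf("x%gcm", sc$sensor_positions)
  write_trace_table(traces, output)
  list(output = basename(output), n_traces = length(traces))
}

stage_calibrate <- function(config, out_dir) {
  if (is.null(config$input)) stop("`calibrate` needs `input`", call. = FALSE)
  d <- utils::read.csv(config$input)
  curve <- fit_calibration(d, response_units = config$response_units %||% "")
  curve_path <- file.path(out_dir, config$curve_output %||% "calibration_curve.json")
  write_calibration_json(curve, curve_path)
  list(sensitivity = curve$sensitivity, intercept = curve$intercept,
       reference_concentration = curve$reference_concentration,
       residual_sd = curve$residual_sd, curve = basename(curve_path))
}

stage_quantify <- function(config, out_dir) {
  if (is.null(config$input) || is.null(config$curve)) {
    stop("`quantify` needs `input` and `curve`", call. = FALSE)
  }
  curve <- read_calibration_json(config$curve)
  traces <- read_trace_table(config$input)
  conc <- lapply(traces, function(tr) {
    vals <- suppressWarnings(invert_response(curve, tr$values))
    trace(tr$times, vals, position = tr$position, kind = tr$kind)
  })
  output <- file.path(out_dir, config$output %||% "concentration_traces.csv")
  write_trace_table(conc, output)
  list(output = basename(output), n_traces = length(conc))
}

stage_fit_flow <- function(config, out_dir) {
  if (is.null(config$input)) stop("`fit-flow` needs `input`", call. = FALSE)
  traces <- read_trace_table(config$input)
  positions <- sort(unique(vapply(traces, function(tr) tr$position, numeric(1))))
  g <- stem_geometry(r = config$r %||% 0.012,
                     source_mM = config$source_mM %||% 75,
                     positions_cm = config$positions_cm %||% positions)
  fit <- fit_flow_rate(traces, g, lateral_tau = config$lateral_tau_s %||% 60)
  list(u_hat = fit$u_hat, residual_rms = fit$residual_rms,
       tau_effective = as.list(fit$tau_effective), tau_mean = fit$tau_mean)
}

stage_kinetics <- function(config, out_dir) {
  if (is.null(config$input) || is.null(config$stimulus_time)) {
    stop("`kinetics` needs `input` and `stimulus_time`", call. = FALSE)
  }
  traces <- read_trace_table(config$input)
  feats <- lapply(traces, function(tr) {
    f <- wave_features(tr, stimulus_time = config$stimulus_time,
                       k = config$k %||% 5,
                       window = config$window %||% 300)
    list(position = tr$position, detected = f$detected, delay = f$delay,
         amplitude = f$amplitude, rise_time = f$rise_time)
  })
  tab <- do.call(rbind, lapply(names(feats), function(nm) {
    f <- feats[[nm]]
    data.frame(channel = nm, position_cm = f$position, detected = f$detected,
               delay_s = f$delay %||% NA, amplitude = f$amplitude,
               rise_time_s = f$rise_time %||% NA)
  }))
  output <- file.path(out_dir, config$output %||% "wave_features.csv")
  utils::write.csv(tab, output, row.names = FALSE, quote = FALSE)
  c(feats, list(output = basename(output)))
}

stage_decay <- function(config) {
  if (!is.null(config$input)) {
    d <- utils::read.csv(config$input)
    x <- d$x; y <- d$y
  } else {
    x <- config$x; y <- config$y
  }
  if (is.null(x) || is.null(y)) {
    stop("`decay` needs `x` and `y` (or `input` CSV with those columns)",
         call. = FALSE)
  }
  fit <- fit_exponential_decay(as.numeric(x), as.numeric(y))
  list(y0 = fit$y0, decay_constant = fit$decay_constant, rms = fit$rms)
}

stage_simulate <- function(config, out_dir) {
  lat <- stem_lattice(
    length_cm = config$length_cm %||% 10,
    dx = config$dx %||% 0.05,
    u = config$u %||% 0.35,
    rbohd_blocked = config$rbohd_blocked,
    ca_channel_blocked = config$ca_channel_blocked)
  ev <- stress_event(position = config$wound_position %||% 5,
                     time = config$wound_time %||% 1,
                     intensity = config$intensity %||% 1)
  sensors <- config$sensors %||% c(4, 6)
  sim <- simulate_mechanism(lat, ev, t_end = config$t_end %||% 40,
                            sensors = sensors)
  output <- file.path(out_dir, config$output %||% "mechanism_traces.csv")
  both <- c(stats::setNames(sim$h2o2, sprintf("h2o2_%gcm", sensors)),
            stats::setNames(sim$vm, sprintf("vp_%gcm", sensors)))
  write_trace_table(both, output)
  list(output = basename(output), sensors = sensors)
}
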