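#' Generate a synthetic calibration table
#'
#' Responses follow the log-linear sensor model
#' `intercept + sensitivity * log10(concentration / reference)` with optional
#' additive Gaussian noise (`noise_sd`, response units) and/or multiplicative
#' noise (`noise_frac`, relative). Reproducible per seed.
#'
#' @param sensitivity slope, response units per decade.
#' @param intercept response at `reference`.
#' @param reference reference concentration (> 0).
#' @param concentrations concentration grid (> 0).
#' @param noise_sd additive noise standard deviation (response units).
#' @param noise_frac multiplicative noise fraction (e.g. 0.01 for 1%).
#' @param seed integer seed or `NULL`.
#' @return data frame with columns `concentration`, `response`.
#' @export
gen_calibration_dataset <- function(sensitivity, intercept = 0, reference = 1,
                                    concentrations, noise_sd = 0,
                                    noise_frac = 0, seed = NULL) {
  check_positive(concentrations, "concentrations")
  check_positive(reference, "reference")
  check_nonnegative(noise_sd, "noise_sd")
  check_nonnegative(noise_frac, "noise_frac")
  resp <- intercept + sensitivity * log10(concentrations / reference)
  with_seed(seed, {
    if (noise_frac > 0) {
      resp <- resp * (1 + stats::rnorm(length(resp), 0, noise_frac))
    }
    if (noise_sd > 0) {
      resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
    }
  })
  data.frame(concentration = concentrations, response = resp)
}

#' Scenario for synthetic stem-transport recordings
#'
#' Mirrors the immersion experiment: a rootless stem placed in a solute bath
#' with sensors implanted above the surface, the stem-average concentration
#' rising as the plug front (speed `u * r`) passes each sensor.
#'
#' @param u xylem flow rate (cm/s).
#' @param r xylem area fraction.
#' @param source_mM bath concentration (mM).
#' @param positions_cm sensor positions (cm).
#' @param lateral_tau front-smoothing constant (s).
#' @param noise_frac multiplicative measurement noise fraction.
#' @param seed integer seed or `NULL`.
#' @return An object of class `"transport_scenario"`.
#' @export
transport_scenario <- function(u = 0.35, r = 0.012, source_mM = 75,
                               positions_cm = c(1, 2), lateral_tau = 60,
                               noise_frac = 0, seed = NULL) {
  check_nonnegative(u, "u")
  check_nonnegative(noise_frac, "noise_frac")
  structure(
    list(geometry = stem_geometry(r, source_mM, positions_cm),
         scenario = flow_scenario(u = u, lateral_tau = lateral_tau),
         noise_frac = noise_frac, seed = seed),
    class = "transport_scenario"
  )
}

#' Generate synthetic stem-average concentration traces
#'
#' Forward-evaluates the 1D convection model at each sensor position and
#' adds multiplicative Gaussian noise.
#'
#' @param scenario a `"transport_scenario"`.
#' @param t_grid sample times (s, >= 0).
#' @return List of concentration `"trace"` objects (kind `"cation"`, mM).
#' @export
gen_transport_traces <- function(scenario, t_grid) {
  stopifnot(inherits(scenario, "transport_scenario"))
  g <- scenario$geometry
  with_seed(scenario$seed, {
    lapply(g$positions_cm, function(x) {
      conc <- convection_concentration(g, scenario$scenario, x, t_grid)
      if (scenario$noise_frac > 0) {
        conc <- conc * (1 + stats::rnorm(length(conc), 0, scenario$noise_frac))
      }
      trace(t_grid, conc, position = x, kind = "cation", units = "mM")
    })
  })
}

#' Scenario for synthetic propagating-wave recordings
#'
#' Parameterises the empirical regularities of stem-propagating H2O2 and
#' variation-potential waves: direction-dependent velocity (downstream,
#' towards the leaves, faster than counterstream), exponential amplitude
#' decay with distance, and a rise time that shortens with amplitude down to
#' a kinetic floor. Defaults are the wound-response figures: velocities
#' 0.39 / 0.16 cm/s, amplitude decay 1.53 cm, rise-time floor 9.9 s.
#'
#' @param stimulus_time stimulus time (s).
#' @param stimulus_position stimulus position (cm); sensor positions are on
#'   the same axis, positive = downstream.
#' @param sensor_positions sensor positions (cm).
#' @param velocity_down,velocity_counter front velocities (cm/s, > 0).
#' @param amplitude0 amplitude extrapolated to the stimulus site (trace units).
#' @param amplitude_decay exponential amplitude decay constant (cm, > 0).
#' @param risetime_floor kinetic floor of the rise time (s, >= 0).
#' @param risetime_prefactor prefactor of the amplitude-dependent rise-time
#'   term (s).
#' @param risetime_scale amplitude scale of the rise-time dependence.
#' @param tail_tau exponential decay constant of the post-peak tail (s).
#' @param noise_sd additive Gaussian noise per sample (trace units).
#' @param fs sampling rate (Hz, default 10).
#' @param t_end recording end (s); default covers the slowest arrival plus
#'   rise and tail.
#' @param kind `"h2o2"` (positive deflection) or `"vp"` (negative,
#'   depolarization plotted downward).
#' @param seed integer seed or `NULL`.
#' @return An object of class `"wave_scenario"`.
#' @export
wave_scenario <- function(stimulus_time = 30, stimulus_position = 0,
                          sensor_positions = c(1, 2),
                          velocity_down = 0.39, velocity_counter = 0.16,
                          amplitude0 = 100, amplitude_decay = 1.53,
                          risetime_floor = 9.9, risetime_prefactor = 40,
                          risetime_scale = 50, tail_tau = 100,
                          noise_sd = 0, fs = 10, t_end = NULL,
                          kind = c("h2o2", "vp"), seed = NULL) {
  check_positive(velocity_down, "velocity_down")
  check_positive(velocity_counter, "velocity_counter")
  check_positive(amplitude0, "amplitude0")
  check_positive(amplitude_decay, "amplitude_decay")
  check_nonnegative(risetime_floor, "risetime_floor")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(fs, "fs")
  kind <- match.arg(kind)
  structure(
    list(stimulus_time = stimulus_time, stimulus_position = stimulus_position,
         sensor_positions = sensor_positions, velocity_down = velocity_down,
         velocity_counter = velocity_counter, amplitude0 = amplitude0,
         amplitude_decay = amplitude_decay, risetime_floor = risetime_floor,
         risetime_prefactor = risetime_prefactor,
         risetime_scale = risetime_scale, tail_tau = tail_tau,
         noise_sd = noise_sd, fs = fs, t_end = t_end, kind = kind,
         seed = seed),
    class = "wave_scenario"
  )
}

# rise phase is A*(1 - exp(-(t-t_on)/tau_r)), capped at 5*tau_r, then an
# exponential tail; 63.2% of the capped peak is crossed 0.98803*tau_r after
# onset, so tau_r is chosen to make (take-off -> 63.2%-of-peak) equal the
# programmed rise time
RISE_CAP <- 5
rise63_factor <- function() -log(1 - 0.632 * (1 - exp(-RISE_CAP)))

#' Generate synthetic propagating-wave traces
#'
#' Each sensor at distance `d` from the stimulus receives a wave whose
#' take-off (5x-baseline threshold crossing) is programmed at
#' `stimulus_time + d / velocity(direction)`, whose amplitude is
#' `amplitude0 * exp(-d / amplitude_decay)`, and whose rise time follows the
#' exponential-with-floor law of the scenario; the waveform is a saturating
#' rise followed by a slow exponential tail. With noise, the onset is
#' shifted so that the mean signal crosses the 5-sigma threshold exactly at
#' the programmed take-off. Passing the output through the wave-kinetics
#' extractors recovers the programmed features to within discretisation
#' error.
#'
#' @param scenario a `"wave_scenario"`.
#' @return List of `"trace"` objects, one per sensor.
#' @examples
#' sc <- wave_scenario(sensor_positions = c(1, 2), noise_sd = 0)
#' trs <- gen_wave_traces(sc)
#' f <- lapply(trs, wave_features, stimulus_time = 30,
#'             baseline = baseline_stats(mean = 0, fluctuation = 1e-9))
#' pair_velocity(f[[1]], f[[2]])  # ~0.39 cm/s
#' @export
gen_wave_traces <- function(scenario) {
  stopifnot(inherits(scenario, "wave_scenario"))
  s <- scenario
  d_all <- abs(s$sensor_positions - s$stimulus_position)
  v_all <- ifelse(s$sensor_positions >= s$stimulus_position,
                  s$velocity_down, s$velocity_counter)
  slowest <- max(d_all / v_all)
  t_end <- if (is.null(s$t_end)) {
    s$stimulus_time + slowest + 5 * (s$risetime_floor + s$risetime_prefactor) + 200
  } else s$t_end
  tt <- seq(0, t_end, by = 1 / s$fs)
  sign <- if (s$kind == "vp") -1 else 1
  with_seed(s$seed, {
    lapply(seq_along(s$sensor_positions), function(i) {
      d <- d_all[i]
      if (d == 0) {
        warning("sensor at the stimulus position: zero-distance wave",
                call. = FALSE)
      }
      t_takeoff <- s$stimulus_time + if (d == 0) 0 else d / v_all[i]
      A <- s$amplitude0 * exp(-d / s$amplitude_decay)
      R <- s$risetime_floor +
        s$risetime_prefactor * exp(-A / s$risetime_scale)
      tau_r <- R / rise63_factor()
      # shift the onset so the mean curve crosses 5*noise_sd at t_takeoff
      delta <- if (s$noise_sd > 0 && 5 * s$noise_sd < A) {
        -tau_r * log(1 - 5 * s$noise_sd / A)
      } else 0
      t_on <- t_takeoff - delta
      t_pk <- t_on + RISE_CAP * tau_r
      vv <- numeric(length(tt))
      rising <- tt > t_on & tt <= t_pk
      vv[rising] <- A * (1 - exp(-(tt[rising] - t_on) / tau_r))
      tail <- tt > t_pk
      vv[tail] <- A * (1 - exp(-RISE_CAP)) * exp(-(tt[tail] - t_pk) / s$tail_tau)
      if (s$noise_sd > 0) {
        vv <- vv + stats::rnorm(length(vv), 0, s$noise_sd)
      }
      trace(tt, sign * vv, position = s$sensor_positions[i], kind = s$kind)
    })
  })
}
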