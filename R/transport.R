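#' Stem geometry for the 1D convection transport model
#'
#' The stem is modelled as a 1D conduit whose cross-section contains a xylem
#' area fraction `r`; the cut stem base sits in a bath of fixed solute
#' concentration. Because the sensor reports the stem-average concentration
#' while transport happens in the xylem, the stem-average front advances at
#' the reduced speed `u * r` (xylem flow rate `u` diluted over the whole
#' cross-section).
#'
#' @param r xylem area fraction, 0 < r < 1 (default 0.012).
#' @param source_mM bath concentration at the stem base, x = 0 (mM).
#' @param positions_cm sensor positions above the bath (cm), > 0, sorted.
#' @return An object of class `"stem_geometry"`.
#' @export
stem_geometry <- function(r = 0.012, source_mM = 75, positions_cm = c(1, 2)) {
  if (!is.finite(r) || r <= 0 || r >= 1) {
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  }
  check_positive(source_mM, "source_mM")
  check_positive(positions_cm, "positions_cm")
  if (is.unsorted(positions_cm, strictly = TRUE)) {
    stop("`positions_cm` must be strictly increasing", call. = FALSE)
  }
  structure(list(r = r, source_mM = source_mM, positions_cm = positions_cm),
            class = "stem_geometry")
}

#' Piecewise-constant xylem flow scenario
#'
#' Flow rate `u(t)` is piecewise constant: `u[i]` holds from `t_change[i]`
#' until `t_change[i+1]` (the last segment extends indefinitely). Plug flow
#' gives a sharp stem-average front; a first-order lateral-equilibration
#' constant `lateral_tau` smooths it, standing in for the fast radial
#' exchange between xylem and the surrounding tissue.
#'
#' @param u flow rate(s), cm/s, >= 0.
#' @param t_change segment start times (s); first must be 0.
#' @param lateral_tau first-order front-smoothing time constant (s, >= 0).
#' @return An object of class `"flow_scenario"`.
#' @export
flow_scenario <- function(u, t_change = 0, lateral_tau = 60) {
  check_nonnegative(u, "u")
  check_nonnegative(lateral_tau, "lateral_tau")
  if (length(u) != length(t_change)) {
    stop("`u` and `t_change` must have equal length", call. = FALSE)
  }
  if (t_change[1] != 0 || is.unsorted(t_change, strictly = TRUE)) {
    stop("`t_change` must start at 0 and increase strictly", call. = FALSE)
  }
  structure(list(u = as.numeric(u), t_change = as.numeric(t_change),
                 lateral_tau = lateral_tau),
            class = "flow_scenario")
}

#' Stem-average front arrival time under piecewise-constant flow
#'
#' Time at which the solute front (advancing at `u(t) * r`) reaches `x`;
#' `Inf` when the flow never carries it that far.
#'
#' @param scenario a `"flow_scenario"`.
#' @param r xylem area fraction.
#' @param x position (cm, > 0).
#' @return Arrival time (s), possibly `Inf`.
#' @export
front_arrival_time <- function(scenario, r, x) {
  check_positive(x, "x")
  u <- scenario$u
  t0 <- scenario$t_change
  n <- length(u)
  travelled <- 0
  for (i in seq_len(n)) {
    t_end <- if (i < n) t0[i + 1] else Inf
    speed <- u[i] * r
    seg_len <- speed * (t_end - t0[i])   # may be Inf or NaN (0 * Inf)
    if (speed == 0) {
      if (i == n) return(Inf)
      next
    }
    if (is.finite(t_end) && travelled + seg_len < x) {
      travelled <- travelled + seg_len
      next
    }
    return(t0[i] + (x - travelled) / speed)
  }
  Inf
}

#' Stem-average concentration under the 1D convection model
#'
#' Solves `dC/dt = -(u * r) * dC/dx` with boundary condition
#' `C(0, t) = source` and a solute-free initial stem, by the method of
#' characteristics (exact for this hyperbolic PDE): the front reaches `x` at
#' [front_arrival_time()], before which the concentration is zero. A
#' positive `lateral_tau` replaces the sharp front with the first-order
#' relaxation `source * (1 - exp(-(t - t_arr)/lateral_tau))`.
#'
#' @param geometry a `"stem_geometry"`.
#' @param scenario a `"flow_scenario"` (its `lateral_tau` is used).
#' @param x measurement position (cm, > 0).
#' @param t time(s) since immersion (s, >= 0); vectorised.
#' @return Concentration(s) in mM, bounded in `[0, source_mM]` and
#'   non-decreasing in `t`.
#' @examples
#' g <- stem_geometry(r = 0.012, source_mM = 75)
#' s <- flow_scenario(u = 0.35, lateral_tau = 0)
#' convection_concentration(g, s, x = 1, t = c(200, 300))  # front at ~238 s
#' @export
convection_concentration <- function(geometry, scenario, x, t) {
  stopifnot(inherits(geometry, "stem_geometry"), inherits(scenario, "flow_scenario"))
  check_positive(x, "x")
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative and finite", call. = FALSE)
  }
  t_arr <- front_arrival_time(scenario, geometry$r, x)
  src <- geometry$source_mM
  tau <- scenario$lateral_tau
  if (!is.finite(t_arr)) return(rep(0, length(t)))
  if (tau <= 0) {
    return(ifelse(t >= t_arr, src, 0))
  }
  ifelse(t >= t_arr, src * (1 - exp(-(t - t_arr) / tau)), 0)
}

#' 1D diffusion null model for stem solute transport
#'
#' Semi-infinite diffusion from a constant-concentration boundary:
#' `C(x, t) = source * erfc(x / (2 * sqrt(D * t)))`. Serves as the null
#' hypothesis against which convection is compared; aqueous K+ diffusion
#' predicts equilibration times of order a day at centimetre distances,
#' orders of magnitude slower than observed.
#'
#' @param D diffusion coefficient (cm^2/s, > 0). The default 1.96e-5 is
#'   aqueous K+ at 25 C.
#' @param source boundary concentration (mM).
#' @param x distance from the boundary (cm, > 0).
#' @param t time(s) (s, > 0); vectorised.
#' @return Concentration(s), same units as `source`.
#' @export
diffusion_concentration <- function(D = 1.96e-5, source = 75, x = 1, t) {
  check_positive(D, "D")
  check_positive(x, "x")
  check_positive(t, "t")
  source * erfc(x / (2 * sqrt(D * t)))
}

#' Time for the diffusion model to reach a fraction of the source
#'
#' Root-finds the unique `t` at which [diffusion_concentration()] equals
#' `fraction * source` at position `x`. Scales as `x^2 / D`.
#'
#' @param D diffusion coefficient (cm^2/s, > 0).
#' @param x distance (cm, > 0).
#' @param fraction target fraction of the source concentration, in (0, 1).
#'   The default 0.632 is the 1 - 1/e criterion used for equilibration
#'   time constants.
#' @return Time in seconds.
#' @examples
#' diffusion_timescale(D = 1.96e-5, x = 1) / 86400  # about 1.3 days
#' @export
diffusion_timescale <- function(D = 1.96e-5, x = 1, fraction = 0.632) {
  check_positive(D, "D")
  check_positive(x, "x")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  f <- function(log_t) erfc(x / (2 * sqrt(D * exp(log_t)))) - fraction
  root <- stats::uniroot(f, lower = log(1e-9), upper = log(1e15), tol = 1e-12)
  exp(root$root)
}

#' Fit the xylem flow rate from stem-average concentration traces
#'
#' Least-squares estimate of a single constant flow rate `u`: minimises the
#' summed squared residual between the measured concentration traces and the
#' 1D convection model across all sensors (bounded scalar optimisation over
#' `[0, u_max]`).
#'
#' @param traces list of concentration `"trace"` objects; each must carry a
#'   `position` present in `geometry$positions_cm`.
#' @param geometry a `"stem_geometry"`.
#' @param lateral_tau front-smoothing constant passed to the model (s).
#' @param u_max upper bound of the search interval (cm/s).
#' @return An object of class `"flow_fit"` with elements `u_hat` (cm/s),
#'   `residual_rms` (mM), `front_arrival` and `tau_effective` (per-sensor
#'   time to reach 63.2% of source, s) and their mean.
#' @examples
#' g <- stem_geometry()
#' sc <- transport_scenario(u = 0.35, lateral_tau = 60)
#' tr <- gen_transport_traces(sc, t_grid = seq(0, 1500, 5))
#' fit_flow_rate(tr, g, lateral_tau = 60)
#' @export
fit_flow_rate <- function(traces, geometry, lateral_tau = 60, u_max = 5) {
  stopifnot(inherits(geometry, "stem_geometry"))
  if (inherits(traces, "trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("need at least one trace", call. = FALSE)
  for (tr in traces) {
    if (!inherits(tr, "trace")) stop("`traces` must be trace objects", call. = FALSE)
    if (!is.finite(tr$position) ||
        !any(abs(geometry$positions_cm - tr$position) < 1e-9)) {
      stop("each trace position must appear in `geometry$positions_cm`",
           call. = FALSE)
    }
  }
  spread <- vapply(traces, function(tr) diff(range(tr$values)), numeric(1))
  if (all(spread < 1e-9 * max(1, geometry$source_mM))) {
    stop("all traces are flat: flow rate is not identifiable", call. = FALSE)
  }
  ssr <- function(u) {
    sc <- flow_scenario(u = u, lateral_tau = lateral_tau)
    sum(vapply(traces, function(tr) {
      pred <- convection_concentration(geometry, sc, tr$position, tr$times)
      sum((tr$values - pred)^2)
    }, numeric(1)))
  }
  opt <- stats::optimize(ssr, interval = c(0, u_max), tol = 1e-9)
  u_hat <- opt$minimum
  if (u_hat > 0.999 * u_max) {
    warning("fitted flow rate is at the search bound `u_max`", call. = FALSE)
  }
  n_tot <- sum(vapply(traces, function(tr) length(tr$times), numeric(1)))
  positions <- vapply(traces, function(tr) tr$position, numeric(1))
  sc_hat <- flow_scenario(u = u_hat, lateral_tau = lateral_tau)
  arr <- vapply(positions, function(x) front_arrival_time(sc_hat, geometry$r, x),
                numeric(1))
  # first-order rise crosses 63.2% of source lateral_tau * (-log(1 - 0.632))
  # seconds after front arrival
  t63 <- arr + lateral_tau * (-log(1 - 0.632))
  names(arr) <- names(t63) <- sprintf("%g cm", positions)
  structure(
    list(u_hat = u_hat, residual_rms = sqrt(opt$objective / n_tot),
         front_arrival = arr, tau_effective = t63,
         tau_mean = mean(t63), lateral_tau = lateral_tau,
         geometry = geometry, n = n_tot),
    class = "flow_fit"
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat(sprintf("<flow_fit> u = %.4g cm/s  (residual RMS %.4g mM over %d samples)\n",
              x$u_hat, x$residual_rms, x$n))
  cat(sprintf("  front arrival: %s s\n",
              paste(sprintf("%s: %.1f", names(x$front_arrival), x$front_arrival),
                    collapse = ", ")))
  cat(sprintf("  time to 63.2%% of source: %s s (mean %.1f)\n",
              paste(sprintf("%.1f", x$tau_effective), collapse = ", "),
              x$tau_mean))
  invisible(x)
}

#' @export
coef.flow_fit <- function(object, ...) c(u_hat = object$u_hat)

#' Detect transpiration (stomatal) events in an inferred flow-rate trace
#'
#' Change-point detection relative to the pre-stimulus baseline: an event
#' starts when `u(t)` departs from the pre-stimulus mean by more than
#' `k` times the pre-stimulus fluctuation, sustained for `persistence`
#' seconds. Departures upward are classified as `"acceleration"` (stomatal
#' opening), downward as `"suppression"` (closure); a return into the band,
#' again sustained, is recorded as `"recovery"`. Onset delays are reported
#' relative to `stimulus_time`; recovery delay relative to the preceding
#' event onset.
#'
#' @param flow a `"trace"` of inferred flow rate u(t) (cm/s).
#' @param stimulus_time stimulus time (s); must lie within the trace span
#'   with a usable baseline before it.
#' @param k detection threshold as a multiple of baseline fluctuation
#'   (default 5, mirroring the wave take-off convention).
#' @param persistence minimum duration the departure must hold (s).
#' @return A data frame with columns `type`, `time_s`, `delay_s`; zero rows
#'   when no event is found.
#' @export
detect_flow_events <- function(flow, stimulus_time, k = 5, persistence = 10) {
  stopifnot(inherits(flow, "trace"))
  tt <- flow$times
  if (stimulus_time < tt[1] || stimulus_time > tt[length(tt)]) {
    stop("`stimulus_time` lies outside the trace span", call. = FALSE)
  }
  base_idx <- tt < stimulus_time
  if (sum(base_idx) < 3L) {
    stop("need at least 3 pre-stimulus samples for a baseline", call. = FALSE)
  }
  m <- mean(flow$values[base_idx])
  s <- max(stats::sd(flow$values[base_idx]), 1e-12)
  out_band <- abs(flow$values - m) > k * s
  idx <- which(tt >= stimulus_time)
  events <- list()
  i <- 1L
  in_event <- FALSE
  onset_time <- NA_real_
  while (i <= length(idx)) {
    j <- idx[i]
    if (!in_event && out_band[j]) {
      # require the departure to persist
      run_end <- j
      while (run_end < length(tt) && out_band[run_end + 1L]) run_end <- run_end + 1L
      if (tt[run_end] - tt[j] >= persistence || run_end == length(tt)) {
        onset_time <- tt[j]
        type <- if (flow$values[j] > m) "acceleration" else "suppression"
        events[[length(events) + 1L]] <-
          data.frame(type = type, time_s = onset_time,
                     delay_s = onset_time - stimulus_time)
        in_event <- TRUE
        i <- match(run_end, idx) + 1L
        next
      } else {
        i <- match(run_end, idx) + 1L
        next
      }
    }
    if (in_event && !out_band[j]) {
      run_end <- j
      while (run_end < length(tt) && !out_band[run_end + 1L]) run_end <- run_end + 1L
      if (tt[run_end] - tt[j] >= persistence || run_end == length(tt)) {
        events[[length(events) + 1L]] <-
          data.frame(type = "recovery", time_s = tt[j],
                     delay_s = tt[j] - onset_time)
        in_event <- FALSE
        i <- match(run_end, idx) + 1L
        next
      } else {
        i <- match(run_end, idx) + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(events) == 0L) {
    return(data.frame(type = character(), time_s = numeric(), delay_s = numeric()))
  }
  do.call(rbind, events)
}
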