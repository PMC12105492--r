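#' Baseline statistics of a pre-stimulus window
#'
#' Wave detection thresholds are expressed as multiples of the baseline
#' fluctuation. The fluctuation is the standard deviation of the linearly
#' detrended pre-stimulus samples (so a slow drift does not inflate it),
#' floored at 1e-12 trace units; a robust alternative uses the scaled median
#' absolute deviation of the detrended samples.
#'
#' @param trace a `"trace"`.
#' @param window length-2 numeric `c(t0, t1)` delimiting the pre-stimulus
#'   window (s); needs at least 10 samples.
#' @param method `"sd"` (default) or `"mad"`.
#' @return An object of class `"baseline_stats"` with elements `window`,
#'   `mean` (baseline level) and `fluctuation`.
#' @export
baseline_fluctuation <- function(trace, window, method = c("sd", "mad")) {
  stopifnot(inherits(trace, "trace"))
  method <- match.arg(method)
  idx <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(idx) < 10L) {
    stop("baseline window holds fewer than 10 samples", call. = FALSE)
  }
  tt <- trace$times[idx]
  vv <- trace$values[idx]
  res <- stats::residuals(stats::lm(vv ~ tt))
  fl <- if (method == "sd") stats::sd(res) else stats::mad(res)
  baseline_stats(window, mean(vv), max(fl, 1e-12), method = method,
                 n = sum(idx))
}

#' Construct baseline statistics directly
#'
#' Used when the baseline level and noise of a channel are known a priori
#' (e.g. the instrument noise floor of a simulated sensor) rather than
#' estimated from a pre-stimulus window.
#'
#' @param window length-2 window (s), may be `c(NA, NA)`.
#' @param mean baseline level (trace units).
#' @param fluctuation baseline fluctuation (trace units, > 0; floored at
#'   1e-12).
#' @param method label of how the fluctuation was obtained.
#' @param n number of samples behind the estimate.
#' @return An object of class `"baseline_stats"`.
#' @export
baseline_stats <- function(window = c(NA_real_, NA_real_), mean = 0,
                           fluctuation, method = "given", n = NA_integer_) {
  if (!is.finite(fluctuation) || fluctuation < 0) {
    stop("`fluctuation` must be non-negative and finite", call. = FALSE)
  }
  structure(list(window = as.numeric(window), mean = mean,
                 fluctuation = max(fluctuation, 1e-12),
                 method = method, n = n),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> mean %.4g, fluctuation %.4g (%s, n = %s)\n",
              x$mean, x$fluctuation, x$method, format(x$n)))
  invisible(x)
}

#' Detect the take-off point of a wave
#'
#' The take-off point is the first post-stimulus sample at which the signal
#' departs from the baseline mean by at least `k` times the baseline
#' fluctuation (default 5), with the departure sustained for `hold` seconds
#' so that single-sample noise spikes do not trigger.
#'
#' @param trace a `"trace"`.
#' @param baseline a `"baseline_stats"`.
#' @param stimulus_time stimulus time (s), inside the trace span.
#' @param k threshold multiple of the fluctuation (default 5).
#' @param hold minimum sustained duration (s); default two sampling
#'   intervals, i.e. three consecutive samples above threshold.
#' @return Take-off time (s), or `NA_real_` when no wave is detected.
#' @export
detect_takeoff <- function(trace, baseline, stimulus_time, k = 5, hold = NULL) {
  stopifnot(inherits(trace, "trace"), inherits(baseline, "baseline_stats"))
  tt <- trace$times
  if (stimulus_time < tt[1] || stimulus_time > tt[length(tt)]) {
    stop("`stimulus_time` lies outside the trace span", call. = FALSE)
  }
  if (is.null(hold)) hold <- 2 * trace_dt(trace)
  th <- k * baseline$fluctuation
  dev <- abs(trace$values - baseline$mean)
  above <- dev >= th & tt >= stimulus_time
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (tt[e] - tt[s] >= hold || e == length(tt)) return(tt[s])
  }
  NA_real_
}

#' Extract kinetic wave features from a trace
#'
#' Summarises a post-stimulus wave by its take-off time (5x-baseline
#' criterion, see [detect_takeoff()]), delay from the stimulus, amplitude
#' (largest absolute departure from the baseline mean within the analysis
#' window, so depolarizations recorded as negative deflections get a
#' positive amplitude), and rise time, the interval from take-off to the
#' signal first reaching 63.2% (1 - 1/e) of its peak departure, with the
#' crossing linearly interpolated between samples.
#'
#' @param trace a `"trace"`.
#' @param stimulus_time stimulus time (s).
#' @param baseline_window pre-stimulus window for [baseline_fluctuation()];
#'   default from the trace start to the stimulus.
#' @param baseline optional precomputed `"baseline_stats"` (overrides
#'   `baseline_window`).
#' @param k take-off threshold multiple (default 5).
#' @param hold sustained-crossing duration (s); see [detect_takeoff()].
#' @param window post-stimulus analysis window for the peak search (s,
#'   default 300, excluding late drift).
#' @return An object of class `"wave_features"`: `detected`, `takeoff_time`,
#'   `delay`, `amplitude`, `rise_time`, `peak_time`, `position`. When no
#'   take-off is found, `detected` is `FALSE` and the timing fields are `NA`
#'   (the amplitude is still reported).
#' @export
wave_features <- function(trace, stimulus_time, baseline_window = NULL,
                          baseline = NULL, k = 5, hold = NULL, window = 300) {
  stopifnot(inherits(trace, "trace"))
  if (is.null(baseline)) {
    if (is.null(baseline_window)) {
      baseline_window <- c(trace$times[1], stimulus_time)
    }
    baseline <- baseline_fluctuation(trace, baseline_window)
  }
  tt <- trace$times
  dev <- abs(trace$values - baseline$mean)
  in_win <- tt >= stimulus_time & tt <= stimulus_time + window
  if (!any(in_win)) stop("no samples in the post-stimulus window", call. = FALSE)
  pk <- which.max(dev * in_win)
  amplitude <- dev[pk]
  takeoff <- detect_takeoff(trace, baseline, stimulus_time, k = k, hold = hold)
  if (is.na(takeoff)) {
    return(structure(
      list(detected = FALSE, takeoff_time = NA_real_, delay = NA_real_,
           amplitude = amplitude, rise_time = NA_real_, peak_time = tt[pk],
           position = trace$position, baseline = baseline, k = k),
      class = "wave_features"
    ))
  }
  level <- 0.632 * amplitude
  after <- which(tt >= takeoff)
  cross_t <- NA_real_
  for (j in after) {
    if (dev[j] >= level) {
      if (j == after[1] || dev[j - 1L] >= level) {
        cross_t <- tt[j]
      } else {
        # linear interpolation of the sub-sample crossing
        f <- (level - dev[j - 1L]) / (dev[j] - dev[j - 1L])
        cross_t <- tt[j - 1L] + f * (tt[j] - tt[j - 1L])
      }
      break
    }
  }
  structure(
    list(detected = TRUE, takeoff_time = takeoff,
         delay = takeoff - stimulus_time, amplitude = amplitude,
         rise_time = cross_t - takeoff, peak_time = tt[pk],
         position = trace$position, baseline = baseline, k = k),
    class = "wave_features"
  )
}

#' @export
print.wave_features <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("<wave_features> no wave detected (peak departure %.4g < %g x fluctuation)\n",
                x$amplitude, x$k))
    return(invisible(x))
  }
  cat(sprintf("<wave_features> take-off %.3f s (delay %.3f s), amplitude %.4g, rise time %.3f s\n",
              x$takeoff_time, x$delay, x$amplitude, x$rise_time))
  if (is.finite(x$position)) cat(sprintf("  position %g cm\n", x$position))
  invisible(x)
}

#' Propagation velocity from a pair of sensors
#'
#' Velocity is the sensor separation divided by the difference of the two
#' take-off times; the wave is assumed to reach the near sensor first.
#'
#' @param f_near `"wave_features"` at the sensor closer to the stimulus.
#' @param f_far `"wave_features"` at the farther sensor.
#' @return Velocity in cm/s. Equal take-off times raise an error; a reversed
#'   ordering (far sensor firing first) warns and returns a negative value.
#' @export
pair_velocity <- function(f_near, f_far) {
  stopifnot(inherits(f_near, "wave_features"), inherits(f_far, "wave_features"))
  if (!isTRUE(f_near$detected) || !isTRUE(f_far$detected)) {
    stop("both sensors need a detected wave to compute a velocity", call. = FALSE)
  }
  dx <- abs(f_far$position - f_near$position)
  if (dx == 0 || is.na(dx)) {
    stop("sensors must sit at distinct positions", call. = FALSE)
  }
  dt <- f_far$takeoff_time - f_near$takeoff_time
  if (dt == 0) {
    stop("identical take-off times: velocity is unbounded", call. = FALSE)
  }
  if (dt < 0) {
    warning("far sensor took off first: check sensor ordering (negative velocity)",
            call. = FALSE)
  }
  dx / dt
}

#' Fit an exponential distance decay
#'
#' Wave amplitude and velocity fall off exponentially with travel distance
#' along the stem; this fits `y = y0 * exp(-x / lambda)` by least squares on
#' `log(y)` followed by a nonlinear refinement on the original scale, and
#' reports `lambda` as the decay constant (cm).
#'
#' @param x distances (cm), at least 3 points.
#' @param y positive values (amplitudes or velocities).
#' @return An object of class `"decay_fit"`: `y0` (extrapolated value at
#'   x = 0), `decay_constant` (cm; `Inf`, flagged, for a non-decaying
#'   series), `rms`. A series that increases with distance yields a negative
#'   decay constant with a warning.
#' @examples
#' x <- 1:4
#' fit_exponential_decay(x, 0.8 * exp(-x / 2.55))
#' @export
fit_exponential_decay <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  check_positive(y, "y")
  lf <- stats::lm(log(y) ~ x)
  slope <- unname(stats::coef(lf)[2])
  y0 <- exp(unname(stats::coef(lf)[1]))
  non_decaying <- slope >= -1e-12
  if (non_decaying) {
    lambda <- if (abs(slope) < 1e-12) Inf else -1 / slope
    if (is.infinite(lambda)) {
      warning("series does not decay with distance (decay constant -> Inf)",
              call. = FALSE)
    } else {
      warning("series increases with distance (negative decay constant)",
              call. = FALSE)
    }
    fitted <- y0 * exp(slope * x)
    return(structure(
      list(y0 = y0, decay_constant = lambda,
           rms = sqrt(mean((y - fitted)^2)), non_decaying = TRUE,
           x = x, y = y, fitted = fitted),
      class = "decay_fit"
    ))
  }
  lambda <- -1 / slope
  nl <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 * exp(-x / lam),
                      start = list(y0 = y0, lam = lambda),
                      lower = c(0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(nl)) {
    cf <- stats::coef(nl)
    y0 <- unname(cf["y0"])
    lambda <- unname(cf["lam"])
  }
  fitted <- y0 * exp(-x / lambda)
  structure(
    list(y0 = y0, decay_constant = lambda,
         rms = sqrt(mean((y - fitted)^2)), non_decaying = FALSE,
         x = x, y = y, fitted = fitted),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y0 = %.4g, decay constant = %.4g cm (RMS %.3g)\n",
              x$y0, x$decay_constant, x$rms))
  if (isTRUE(x$non_decaying)) cat("  flagged: series not decaying\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(y0 = object$y0, decay_constant = object$decay_constant)
}

#' @export
predict.decay_fit <- function(object, x, ...) {
  object$y0 * exp(-x / object$decay_constant)
}

#' Fit the rise-time floor (kinetic limit) against amplitude
#'
#' Rise times shorten as wave amplitude grows but cannot fall below the
#' kinetic limit of the underlying generation machinery. This fits
#' `rise_time = floor + prefactor * exp(-amplitude / scale)` by bounded
#' nonlinear least squares (`floor >= 0`) and reports `floor` as the
#' extrapolated minimum rise time.
#'
#' @param amplitudes wave amplitudes (any consistent units), >= 4 points.
#' @param rise_times corresponding rise times (s, > 0).
#' @return An object of class `"risetime_fit"`: `floor` (s), `prefactor`
#'   (s), `scale` (amplitude units), `rms`. Constant rise times return
#'   `floor` equal to their common value with `prefactor = 0`.
#' @examples
#' a <- seq(5, 60, length.out = 8)
#' fit_risetime_floor(a, 9.9 + 30 * exp(-a / 20))
#' @export
fit_risetime_floor <- function(amplitudes, rise_times) {
  if (length(amplitudes) != length(rise_times)) {
    stop("`amplitudes` and `rise_times` must have equal length", call. = FALSE)
  }
  if (length(amplitudes) < 4L) stop("need at least 4 points", call. = FALSE)
  check_positive(rise_times, "rise_times")
  A <- as.numeric(amplitudes)
  r <- as.numeric(rise_times)
  if (stats::sd(r) < 1e-12 * max(abs(r))) {
    return(structure(
      list(floor = mean(r), prefactor = 0, scale = NA_real_, rms = 0,
           amplitudes = A, rise_times = r, fitted = rep(mean(r), length(r))),
      class = "risetime_fit"
    ))
  }
  fit <- NULL
  for (frac in c(0.95, 0.8, 0.5, 0)) {
    f0 <- frac * min(r)
    lz <- log(pmax(r - f0, 1e-9))
    lf <- stats::lm(lz ~ A)
    sl <- unname(stats::coef(lf)[2])
    b0 <- if (sl < -1e-12) -1 / sl else diff(range(A)) / 2
    a0 <- max(exp(unname(stats::coef(lf)[1])), 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ fl + a * exp(-A / b),
                        start = list(fl = f0, a = a0, b = b0),
                        lower = c(0, 0, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("rise-time floor fit did not converge; residual spread ",
         sprintf("%.3g", stats::sd(r)), call. = FALSE)
  }
  cf <- stats::coef(fit)
  fitted <- unname(cf["fl"]) + unname(cf["a"]) * exp(-A / unname(cf["b"]))
  structure(
    list(floor = unname(cf["fl"]), prefactor = unname(cf["a"]),
         scale = unname(cf["b"]), rms = sqrt(mean((r - fitted)^2)),
         amplitudes = A, rise_times = r, fitted = fitted),
    class = "risetime_fit"
  )
}

#' @export
print.risetime_fit <- function(x, ...) {
  cat(sprintf("<risetime_fit> floor = %.4g s, prefactor = %.4g s, amplitude scale = %.4g (RMS %.3g)\n",
              x$floor, x$prefactor, x$scale, x$rms))
  invisible(x)
}

#' @export
coef.risetime_fit <- function(object, ...) {
  c(floor = object$floor, prefactor = object$prefactor, scale = object$scale)
}
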