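#' Construct a log-linear calibration curve
#'
#' fOECT sensors respond linearly in the logarithm of analyte concentration:
#' `response = intercept + sensitivity * log10(concentration / reference)`.
#' `sensitivity` is the response change per decade of concentration and
#' `intercept` the response at `reference_concentration`.
#'
#' @param sensitivity response change per decade (units/dec).
#' @param intercept response at the reference concentration.
#' @param reference_concentration concentration at which the intercept
#'   applies (> 0).
#' @param response_units free-text label for the response axis.
#' @param valid_range length-2 concentration range covered by the fit, or
#'   `NULL` when unknown; evaluation outside it warns (extrapolation).
#' @return An object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(sensitivity, intercept = 0,
                              reference_concentration = 1,
                              response_units = "",
                              valid_range = NULL) {
  if (!is.finite(sensitivity)) stop("`sensitivity` must be finite", call. = FALSE)
  check_positive(reference_concentration, "reference_concentration")
  if (!is.null(valid_range)) {
    valid_range <- as.numeric(valid_range)
    if (length(valid_range) != 2L || any(valid_range <= 0) ||
        valid_range[1] >= valid_range[2]) {
      stop("`valid_range` must be c(min, max) with 0 < min < max", call. = FALSE)
    }
  }
  invertible <- abs(sensitivity) > 1e-15
  if (!invertible) {
    warning("zero sensitivity: curve is flat and not invertible", call. = FALSE)
  }
  structure(
    list(sensitivity = sensitivity, intercept = intercept,
         reference_concentration = reference_concentration,
         response_units = response_units, valid_range = valid_range,
         invertible = invertible, n = NA_integer_, residual_sd = NA_real_),
    class = "calibration_curve"
  )
}

#' Fit a log-linear calibration curve
#'
#' Ordinary least squares of sensor response on log10(concentration). The
#' reference concentration of the returned curve is the lowest measured
#' concentration, so the intercept is the fitted blank-level response there;
#' this is also the blank used by [detection_limit()].
#'
#' Either pass a data frame with columns `concentration` and `response`, or
#' two numeric vectors.
#'
#' @param concentration numeric vector of concentrations (> 0), or a data
#'   frame holding both columns.
#' @param response numeric vector of sensor responses (ignored when
#'   `concentration` is a data frame).
#' @param response_units label stored on the curve (e.g. `"uA"`, `"mA"`, `"%"`).
#' @return A `"calibration_curve"` with `sensitivity` = fitted slope
#'   (units/dec), `valid_range` = range of input concentrations, plus the
#'   underlying `lm` fit in `$fit`.
#' @examples
#' pts <- gen_calibration_dataset(116.7, reference = 75,
#'                                concentrations = 75 * 10^seq(-2, 0, 0.5))
#' fit_calibration(pts, response_units = "uA")
#' @export
fit_calibration <- function(concentration, response = NULL, response_units = "") {
  if (is.data.frame(concentration)) {
    d <- concentration
    if (!all(c("concentration", "response") %in% names(d))) {
      stop("data frame must have columns `concentration` and `response`",
           call. = FALSE)
    }
    concentration <- d$concentration
    response <- d$response
  }
  check_positive(concentration, "concentration")
  if (length(concentration) != length(response)) {
    stop("`concentration` and `response` must have equal length", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("need at least 2 distinct concentrations to fit a line", call. = FALSE)
  }
  lc <- log10(concentration)
  fit <- stats::lm(response ~ lc)
  slope <- unname(stats::coef(fit)[2])
  ref <- min(concentration)
  intercept <- unname(stats::coef(fit)[1]) + slope * log10(ref)
  curve <- calibration_curve(slope, intercept, ref, response_units,
                             valid_range = range(concentration))
  curve$fit <- fit
  curve$n <- length(concentration)
  curve$residual_sd <- stats::sigma(fit)
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  u <- if (nzchar(x$response_units)) x$response_units else "units"
  cat(sprintf("<calibration_curve> sensitivity %.6g %s/dec\n", x$sensitivity, u))
  cat(sprintf("  intercept %.6g %s at reference concentration %.4g\n",
              x$intercept, u, x$reference_concentration))
  if (!is.null(x$valid_range)) {
    cat(sprintf("  fitted over [%.4g, %.4g]\n", x$valid_range[1], x$valid_range[2]))
  }
  if (!x$invertible) cat("  flat (non-invertible) curve\n")
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(sensitivity = object$sensitivity, intercept = object$intercept,
    reference_concentration = object$reference_concentration)
}

#' Predict sensor response at given concentrations
#'
#' Forward evaluation of the fitted log-linear curve. Evaluation outside the
#' curve's `valid_range` warns (extrapolation) but proceeds.
#'
#' @param object a `"calibration_curve"`.
#' @param concentration concentrations (> 0) at which to evaluate.
#' @param ... unused.
#' @return Predicted responses, same length as `concentration`.
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  check_positive(concentration, "concentration")
  warn_if_outside_range(object, concentration)
  object$intercept +
    object$sensitivity * log10(concentration / object$reference_concentration)
}

warn_if_outside_range <- function(curve, concentration) {
  vr <- curve$valid_range
  if (!is.null(vr) && any(concentration < vr[1] | concentration > vr[2])) {
    warning(sprintf(
      "concentration outside calibrated range [%.4g, %.4g]: extrapolating",
      vr[1], vr[2]), call. = FALSE)
  }
}

#' Invert a calibration curve: response to concentration
#'
#' Solves the log-linear model for concentration,
#' `10^((response - intercept) / sensitivity) * reference_concentration`.
#' Round-trips with [predict.calibration_curve()] to floating tolerance.
#'
#' @param curve a `"calibration_curve"` with nonzero sensitivity.
#' @param response sensor response(s) to invert.
#' @return Concentration(s) in the curve's concentration units.
#' @export
invert_response <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$invertible) {
    stop("curve has zero sensitivity and cannot be inverted", call. = FALSE)
  }
  conc <- 10^((response - curve$intercept) / curve$sensitivity) *
    curve$reference_concentration
  warn_if_outside_range(curve, conc)
  conc
}

#' Signal-to-noise detection limit of a calibrated sensor
#'
#' The concentration at which the predicted response exceeds the blank level
#' (the curve's intercept, referenced to the lowest measured concentration)
#' by `snr` times the baseline noise. This is the extrapolated S/N criterion
#' commonly quoted for electrochemical sensors (S/N = 3 by default):
#' `LOD = reference * 10^(snr * noise_sd / |sensitivity|)`.
#'
#' @param curve a `"calibration_curve"` with nonzero sensitivity.
#' @param noise_sd standard deviation of the blank response (same units as
#'   the response axis), >= 0.
#' @param snr signal-to-noise ratio defining detection (default 3).
#' @return Detection-limit concentration. With `noise_sd = 0` the degenerate
#'   bound (the blank reference concentration itself) is returned with a
#'   warning.
#' @export
detection_limit <- function(curve, noise_sd, snr = 3) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$invertible) {
    stop("curve has zero sensitivity: no detection limit", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative and finite", call. = FALSE)
  }
  check_positive(snr, "snr")
  if (noise_sd == 0) {
    warning("noise_sd = 0: degenerate detection limit (blank bound)",
            call. = FALSE)
    return(curve$reference_concentration)
  }
  curve$reference_concentration *
    10^(snr * noise_sd / abs(curve$sensitivity))
}
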