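#' Construct a sensor trace
#'
#' A trace is one channel of a stem-implanted sensor: sampled times (seconds
#' from recording start) and values (source-drain current, percentage change,
#' membrane potential in mV, concentration, or inferred flow rate), together
#' with the sensor position along the stem. Distances are signed centimetres
#' from the stimulus site, positive towards the leaves (downstream of the
#' transpiration-driven xylem flow).
#'
#' @param times numeric vector of sample times (s), strictly increasing.
#' @param values numeric vector, same length as `times`, all finite.
#' @param position sensor position along the stem (cm), may be `NA`.
#' @param kind signal label, e.g. `"h2o2"`, `"vp"`, `"cation"`, `"flow"`.
#' @param units free-text unit label for `values`.
#' @return An object of class `"trace"`.
#' @examples
#' tr <- trace(seq(0, 10, by = 0.1), sin(seq(0, 10, by = 0.1)), position = 1)
#' print(tr)
#' @export
trace <- function(times, values, position = NA_real_, kind = "h2o2", units = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  dt <- diff(times)
  if (any(!is.finite(times)) || any(dt <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("`values` must all be finite", call. = FALSE)
  structure(
    list(times = times, values = values, position = as.numeric(position)[1],
         kind = as.character(kind)[1], units = as.character(units)[1]),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s  %d samples  t = [%.3g, %.3g] s", x$kind,
              length(x$times), x$times[1], x$times[length(x$times)]))
  if (is.finite(x$position)) cat(sprintf("  position = %g cm", x$position))
  if (nzchar(x$units)) cat(sprintf("  [%s]", x$units))
  cat("\n")
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$times)

# median sampling interval, used for sample-count based defaults
trace_dt <- function(tr) stats::median(diff(tr$times))
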