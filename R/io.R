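#' Read a trace table
#'
#' Trace tables are comma-separated text with a header row and columns
#' `time_s`, `channel`, `value`, plus optional `position_cm` and `kind`.
#' One trace is returned per channel; times must increase strictly within
#' each channel.
#'
#' @param path file path.
#' @return Named list of `"trace"` objects, one per channel.
#' @export
read_trace_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "channel", "value")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("trace table is missing column `%s`", missing[1]), call. = FALSE)
  }
  channels <- unique(d$channel)
  out <- lapply(channels, function(ch) {
    rows <- which(d$channel == ch)
    tt <- d$time_s[rows]
    if (any(diff(tt) <= 0)) {
      bad <- rows[which(diff(tt) <= 0)[1] + 1L]
      stop(sprintf("non-increasing time in channel `%s` at row %d", ch, bad),
           call. = FALSE)
    }
    pos <- if ("position_cm" %in% names(d)) d$position_cm[rows][1] else NA_real_
    kind <- if ("kind" %in% names(d)) d$kind[rows][1] else "unknown"
    trace(tt, d$value[rows], position = pos, kind = kind)
  })
  names(out) <- channels
  out
}

#' Write traces to a trace table
#'
#' Inverse of [read_trace_table()]; the written file round-trips losslessly.
#'
#' @param traces named list of `"trace"` objects (unnamed lists get
#'   `ch1`, `ch2`, ... channel names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  nm <- names(traces)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- sprintf("ch%d", seq_along(traces))
  }
  rows <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(time_s = tr$times, channel = nm[i], value = tr$values,
               position_cm = tr$position, kind = tr$kind)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a calibration curve to JSON
#'
#' @param curve a `"calibration_curve"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  doc <- curve[c("sensitivity", "intercept", "reference_concentration",
                 "response_units", "valid_range", "invertible")]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path a JSON file written by [write_calibration_json()].
#' @return A `"calibration_curve"`.
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(doc$sensitivity, doc$intercept,
                    doc$reference_concentration,
                    response_units = doc$response_units %||% "",
                    valid_range = doc$valid_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
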