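# Uniformly sampled multichannel recordings (position / command / current).

#' Construct a trace recording
#'
#' A uniformly sampled multichannel time series: bundle position (nm),
#' stimulus command, and optionally transduction current (pA). Sampling rates
#' between 2.5 and 25 kHz are accepted.
#'
#' @param dt sampling interval (s).
#' @param position position channel (nm), or NULL.
#' @param command command channel, or NULL. Units recorded in
#'   `command_units` ("V", or "pN" when the stimulus is expressed directly as
#'   effective force).
#' @param current current channel (pA), or NULL.
#' @param annotations named list of event times (s), e.g. `step_on`.
#' @param command_units unit label for the command channel.
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(dt, position = NULL, command = NULL, current = NULL,
                            annotations = list(), command_units = "V") {
  check_positive(dt, "dt")
  fs <- 1 / dt
  if (fs < 2500 - 1e-9 || fs > 25000 + 1e-9)
    warning(sprintf("sampling rate %.3g kHz outside the 2.5-25 kHz acquisition range", fs / 1000))
  chans <- Filter(Negate(is.null), list(position = position, command = command, current = current))
  if (!length(chans)) stop_input("at least one channel is required")
  n <- unique(vapply(chans, length, integer(1)))
  if (length(n) != 1) stop_input("all channels must have equal length")
  structure(
    list(dt = dt, position = position, command = command, current = current,
         annotations = annotations, command_units = command_units),
    class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  chans <- names(Filter(Negate(is.null), x[c("position", "command", "current")]))
  n <- length(x[[chans[1]]])
  cat(sprintf("<trace_recording> %d samples @ %.3g kHz (%.3g s), channels: %s\n",
              n, 1e-3 / x$dt, n * x$dt, paste(chans, collapse = ", ")))
  if (length(x$annotations))
    cat("  annotations:", paste(sprintf("%s=%.4gs", names(x$annotations),
                                        unlist(x$annotations)), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of a trace
#'
#' @param trace a [trace_recording()].
#' @return Sample times in seconds, starting at 0.
#' @export
trace_time <- function(trace) {
  n <- length(Filter(Negate(is.null), trace[c("position", "command", "current")])[[1]])
  (seq_len(n) - 1) * trace$dt
}

#' Write / read a trace as delimited text with a JSON sidecar
#'
#' The channels go to `<path>` as CSV (time_s plus one column per channel);
#' dt, channel names, command units and annotations go to `<path>.json`.
#'
#' @param trace a [trace_recording()].
#' @param path CSV file path.
#' @return `read_trace` returns a `trace_recording`.
#' @export
write_trace <- function(trace, path) {
  chans <- Filter(Negate(is.null), trace[c("position", "command", "current")])
  df <- data.frame(time_s = trace_time(trace), chans)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dt = trace$dt, channels = names(chans),
         command_units = trace$command_units, annotations = trace$annotations),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trace_recording(dt = meta$dt,
                  position = if ("position" %in% names(df)) df$position,
                  command = if ("command" %in% names(df)) df$command,
                  current = if ("current" %in% names(df)) df$current,
                  annotations = as.list(meta$annotations),
                  command_units = meta$command_units)
}
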