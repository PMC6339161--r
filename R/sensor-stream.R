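#' Construct a sensor stream
#'
#' A sensor stream is one device channel group: a strictly increasing time
#' axis in seconds plus one or more real-valued channels sampled at a declared
#' rate. Stream identifiers follow the field's symbol grammar, e.g. `"p^pulse"`
#' (photoplethysmogram), `"a^S3"` (chest accelerometer), `"r^BT"` (buttocks
#' rotation angles), `"u^PD"` (pupil diameter).
#'
#' @param stream_id character scalar identifier
#' @param rate_hz declared sampling rate (Hz), > 0
#' @param times numeric vector of sample times (seconds), strictly increasing
#' @param values numeric vector or matrix (one column per channel)
#' @param channels optional channel names (e.g. `c("x","y","z")`)
#' @return an object of class `sensor_stream`
#' @export
sensor_stream <- function(stream_id, rate_hz, times, values, channels = NULL) {
  if (!is.character(stream_id) || length(stream_id) != 1L) {
    stop("`stream_id` must be a single string", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  values <- as.matrix(values)
  if (length(times) != nrow(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(channels)) colnames(values) <- channels
  structure(
    list(stream_id = stream_id, rate_hz = rate_hz,
         times = as.numeric(times), values = values),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s  %g Hz  %d samples x %d channel(s)  [%.2f, %.2f] s\n",
              x$stream_id, x$rate_hz, nrow(x$values), ncol(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

stream_duration <- function(stream) {
  diff(range(stream$times)) + 1 / stream$rate_hz
}

# regular time axis helper: n samples at rate starting at 0
stream_times <- function(duration_s, rate_hz) {
  n <- floor(duration_s * rate_hz)
  seq(0, by = 1 / rate_hz, length.out = n)
}

stream_channel <- function(stream, channel) {
  if (is.character(channel)) {
    idx <- match(channel, colnames(stream$values))
    if (is.na(idx)) stop(sprintf("stream %s has no channel '%s'", stream$stream_id, channel),
                         call. = FALSE)
  } else {
    idx <- channel
  }
  stream$values[, idx]
}

#' Validate the internal consistency of a sensor stream
#'
#' Checks the declared rate against the median time step (within 1%) and the
#' time/value length contract.
#'
#' @param stream a [sensor_stream()]
#' @return `TRUE` invisibly, or an error describing the violation
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (length(stream$times) != nrow(stream$values)) {
    stop("times/values length mismatch", call. = FALSE)
  }
  if (length(stream$times) > 2L) {
    step <- median(diff(stream$times))
    if (abs(step - 1 / stream$rate_hz) > 0.01 / stream$rate_hz) {
      stop(sprintf("stream %s: declared rate %g Hz inconsistent with median step %g s",
                   stream$stream_id, stream$rate_hz, step), call. = FALSE)
    }
  }
  invisible(TRUE)
}
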