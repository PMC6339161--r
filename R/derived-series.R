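#' Construct a derived series
#'
#' Derived series are secondary signals computed from raw streams: the RR
#' interval sequence, 1 Hz sliding-window HRV band powers (VLF/LF/HF/TP),
#' instantaneous heart rate, and 1 Hz sliding-window sample entropy and
#' largest Lyapunov exponent of inertial streams. Windowed kinds follow the
#' 30 s window / 1 s slide contract: `floor(duration) - 29` values for a
#' fully covered recording.
#'
#' @param kind one of `"RR"`, `"HR"`, `"VLF"`, `"LF"`, `"HF"`, `"TP"`,
#'   `"entropy"`, `"lyapunov"`
#' @param source stream id the series derives from
#' @param rate_hz nominal rate (1 for windowed kinds, `NA` for event series)
#' @param times sample times in seconds
#' @param values numeric values (may contain `NA` for windows flagged missing)
#' @return an object of class `derived_series`
#' @export
derived_series <- function(kind, source, rate_hz, times, values) {
  stopifnot(length(times) == length(values))
  structure(list(kind = kind, source = source, rate_hz = rate_hz,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "derived_series")
}

#' @export
print.derived_series <- function(x, ...) {
  cat(sprintf("<derived_series> %s from %s: %d values\n",
              x$kind, x$source, length(x$values)))
  invisible(x)
}

# window start offsets for the 30 s / 1 s sliding contract
sliding_starts <- function(t0, t1, width = 30, step = 1) {
  span <- t1 - t0
  n <- floor(span + 1e-9) - width + step
  if (n < 1) return(numeric(0))
  t0 + seq(0, by = step, length.out = n)
}
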