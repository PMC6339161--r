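#' Detect beats and RR intervals from a pulse wave
#'
#' Band-passes the photoplethysmogram to 0.5--8 Hz (3rd-order Butterworth,
#' zero-phase), picks local maxima above an adaptive amplitude floor, and
#' enforces a 250 ms refractory period (keeping the larger peak of any
#' conflicting pair). RR intervals are the successive onset differences in
#' milliseconds; each interval is timestamped at the beat that closes it.
#'
#' @param pulse a 1000 Hz pulse [sensor_stream()]
#' @param refractory_s minimum beat spacing (default 0.25 s)
#' @return a [derived_series()] of kind `"RR"` (times = closing beat, values
#'   = RR in ms) with attribute `beat_times`
#' @export
detect_rr <- function(pulse, refractory_s = 0.25) {
  stopifnot(inherits(pulse, "sensor_stream"))
  if (stream_duration(pulse) < 30) {
    stop("pulse recording must cover at least 30 s", call. = FALSE)
  }
  x <- as.numeric(pulse$values[, 1])
  rate <- pulse$rate_hz
  bf <- signal::butter(3, c(0.5, 8) / (rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  n <- length(xf)
  peak <- which(xf[2:(n - 1)] > xf[1:(n - 2)] & xf[2:(n - 1)] >= xf[3:n]) + 1L
  floor_amp <- 0.4 * quantile(xf, 0.98, names = FALSE)
  peak <- peak[xf[peak] > max(floor_amp, 1e-6)]
  if (length(peak) < 2L) stop("no beats found in pulse wave", call. = FALSE)
  # refractory rule: scan peaks by amplitude, drop any within refractory_s
  ord <- peak[order(xf[peak], decreasing = TRUE)]
  keep_t <- numeric(0)
  keep <- integer(0)
  for (p in ord) {
    tp <- pulse$times[p]
    if (!length(keep_t) || min(abs(keep_t - tp)) > refractory_s) {
      keep <- c(keep, p)
      keep_t <- c(keep_t, tp)
    }
  }
  beats <- sort(pulse$times[keep])
  if (length(beats) < 2L) stop("no beats found in pulse wave", call. = FALSE)
  rr <- diff(beats) * 1000
  out <- derived_series("RR", pulse$stream_id, NA_real_, beats[-1L], rr)
  attr(out, "beat_times") <- beats
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# one-sided Hann periodogram, rescaled so that sum(power) equals the
# population variance of the input exactly (total-power preserving)
periodogram_power <- function(x) {
  n <- length(x)
  w <- hann_window(n)
  xc <- x - mean(x)
  xw <- xc * w
  X <- fft(xw)
  p <- Mod(X)^2 / (n * sum(w^2))
  tot <- sum(p)
  if (tot > 0) p <- p * (sum(xc^2) / n) / tot
  half <- floor(n / 2)
  pw <- p[1:(half + 1)]
  # fold the negative frequencies onto 1..half (skip DC; Nyquist unpaired)
  if (n %% 2 == 0) {
    if (half > 1) pw[2:half] <- pw[2:half] + rev(p[(half + 2):n])
  } else {
    pw[2:(half + 1)] <- pw[2:(half + 1)] + rev(p[(half + 2):n])
  }
  list(freq = (0:half) / n, power = pw)  # freq in cycles/sample
}

hrv_bands <- list(VLF = c(0, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4))

#' Sliding-window HRV band-power series
#'
#' Resamples an RR series to uniform 4 Hz by linear interpolation, slides a
#' 30 s window at 1 s steps, and integrates the Hann-windowed periodogram
#' over the requested band: VLF at 0.04 Hz or less, LF 0.04--0.15 Hz, HF
#' 0.15--0.4 Hz, with TP defined as the sum VLF + LF + HF. The result is a
#' 1 Hz series of band powers (ms^2), one value per fully covered window.
#'
#' @param rr a [detect_rr()] result (or any `derived_series` of RR ms)
#' @param band `"VLF"`, `"LF"`, `"HF"` or `"TP"`
#' @param resample_hz uniform resampling rate (default 4 Hz)
#' @return a 1 Hz [derived_series()] of band power, timestamped at window end
#' @export
hrv_band_series <- function(rr, band = c("VLF", "LF", "HF", "TP"),
                            resample_hz = 4) {
  band <- match.arg(band)
  stopifnot(inherits(rr, "derived_series"))
  span <- diff(range(rr$times))
  if (span < 30) stop("RR span shorter than one 30 s window", call. = FALSE)
  t0 <- min(rr$times)
  grid <- seq(t0, max(rr$times), by = 1 / resample_hz)
  rru <- approx(rr$times, rr$values, xout = grid, rule = 2)$y
  starts <- sliding_starts(t0, max(rr$times))
  if (!length(starts)) stop("RR span shorter than one 30 s window", call. = FALSE)
  win_n <- 30 * resample_hz
  vals <- vapply(starts, function(s) {
    i0 <- which.min(abs(grid - s))
    idx <- i0:(i0 + win_n - 1L)
    idx <- idx[idx <= length(rru)]
    pg <- periodogram_power(rru[idx])
    f_hz <- pg$freq * resample_hz
    band_power <- function(b) {
      lim <- hrv_bands[[b]]
      sum(pg$power[f_hz > lim[1] & f_hz <= lim[2]])
    }
    if (band == "TP") {
      band_power("VLF") + band_power("LF") + band_power("HF")
    } else {
      band_power(band)
    }
  }, numeric(1))
  derived_series(band, rr$source, 1, starts + 30, vals)
}

#' Uniform 1 Hz RR and heart-rate series
#'
#' Linear interpolation of the detected RR intervals onto a 1 s grid;
#' heart rate is the instantaneous `60000 / RR` (beats per minute).
#'
#' @param rr a [detect_rr()] result
#' @return list with elements `RR` and `HR`, both 1 Hz [derived_series()]
#' @export
rr_rate_series <- function(rr) {
  stopifnot(inherits(rr, "derived_series"))
  grid <- seq(ceiling(min(rr$times)), floor(max(rr$times)), by = 1)
  v <- approx(rr$times, rr$values, xout = grid, rule = 2)$y
  list(RR = derived_series("RR", rr$source, 1, grid, v),
       HR = derived_series("HR", rr$source, 1, grid, 60000 / v))
}
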