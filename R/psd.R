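#' Binned power-spectral-density features
#'
#' The spectral feature `f(series, freq)` is the power density of the
#' Hann-windowed periodogram aggregated onto a fixed frequency grid whose bin
#' width is one twentieth of the Nyquist frequency; the feature battery
#' evaluates it at multiples of Nyquist/10 (the declared frequency
#' resolution), all of which lie on that grid. Density units are
#' power per Hz, so summing `density * bin_width` over all bins recovers the
#' series variance (Parseval).
#'
#' @param values numeric series
#' @param rate_hz sampling rate of the series
#' @return `psd_bins()`: data.frame with `freq` (bin centers, Hz) and
#'   `density`; `psd_feature()`: a single density value
#' @export
psd_bins <- function(values, rate_hz) {
  values <- values[is.finite(values)]
  n <- length(values)
  nyq <- rate_hz / 2
  dfreq <- nyq / 20
  centers <- seq(0, nyq, by = dfreq)
  if (n < 4L) {
    return(data.frame(freq = centers, density = rep(NA_real_, length(centers))))
  }
  pg <- periodogram_power(values)
  f_hz <- pg$freq * rate_hz
  bin <- pmin(round(f_hz / dfreq), length(centers) - 1L) + 1L
  dens <- vapply(seq_along(centers), function(b) {
    sum(pg$power[bin == b]) / dfreq
  }, numeric(1))
  data.frame(freq = centers, density = dens)
}

#' @rdname psd_bins
#' @param target_freq_hz requested frequency; must lie on the Nyquist/20 grid
#'   and in (0, Nyquist\]
#' @export
psd_feature <- function(values, rate_hz, target_freq_hz) {
  nyq <- rate_hz / 2
  dfreq <- nyq / 20
  if (!is.numeric(target_freq_hz) || length(target_freq_hz) != 1L ||
      target_freq_hz <= 0 || target_freq_hz > nyq) {
    stop("`target_freq_hz` must lie in (0, Nyquist]", call. = FALSE)
  }
  k <- target_freq_hz / dfreq
  if (abs(k - round(k)) > 1e-8) {
    stop(sprintf("`target_freq_hz` = %g is off the Nyquist/20 grid (spacing %g Hz)",
                 target_freq_hz, dfreq), call. = FALSE)
  }
  bins <- psd_bins(values, rate_hz)
  bins$density[round(k) + 1L]
}
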