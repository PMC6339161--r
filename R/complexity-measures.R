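#' Sample entropy of a series
#'
#' Richman--Moorman sample entropy: the negative log of the conditional
#' probability that templates of length `m` matching within Chebyshev
#' tolerance `r` still match at length `m + 1`. Lower values indicate more
#' regular dynamics.
#'
#' @param values numeric series
#' @param m template length (default 2)
#' @param r tolerance; defaults to `r_frac * sd(values)`
#' @param r_frac tolerance as a fraction of the series SD (default 0.2)
#' @return a single entropy value (`NA` for degenerate input)
#' @export
sample_entropy <- function(values, m = 2L, r = NULL, r_frac = 0.2) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) values <- values[is.finite(values)]
  s <- sd(values)
  if (!length(values) || is.na(s) || s == 0) return(NA_real_)
  if (is.null(r)) r <- r_frac * s
  sampen_cpp(values, as.integer(m), r)
}

#' Largest Lyapunov exponent of a series (Rosenstein method)
#'
#' Embeds the series (dimension `emb_dim`, lag `delay`), finds each point's
#' nearest neighbour outside a Theiler exclusion window, and fits the slope
#' of the mean log-divergence curve over the first `fit_steps` steps. The
#' returned exponent is per second (slope divided by `dt`); for map data use
#' `dt = 1` to obtain the per-step exponent.
#'
#' @param values numeric series
#' @param dt sampling interval in seconds
#' @param emb_dim embedding dimension (default 3)
#' @param delay embedding lag in samples; default = first zero crossing of
#'   the autocorrelation function
#' @param fit_steps divergence horizon used for the linear fit; default
#'   covers 0.5 s
#' @param theiler temporal exclusion window in samples (default `max(delay,
#'   fit_steps)`)
#' @return the largest Lyapunov exponent (per second), `NA` if degenerate
#' @export
lyapunov_exponent <- function(values, dt, emb_dim = 3L, delay = NULL,
                              fit_steps = NULL, theiler = NULL) {
  values <- as.numeric(values)
  if (length(values) < 20L) return(NA_real_)
  if (sd(values) <= 1e-10 * (1 + abs(mean(values)))) return(NA_real_)
  if (is.null(delay)) delay <- first_acf_zero(values)
  if (is.null(fit_steps)) fit_steps <- max(2L, round(0.5 / dt))
  if (is.null(theiler)) theiler <- max(delay, fit_steps)
  # ignore numerically duplicate neighbours (exactly periodic signals)
  min_d2 <- 1e-12 * var(values)
  div <- rosenstein_divergence_cpp(values, as.integer(emb_dim), as.integer(delay),
                                   as.integer(fit_steps), as.integer(theiler),
                                   min_d2)
  if (!length(div) || any(!is.finite(div))) return(NA_real_)
  tt <- seq_along(div) - 1
  slope <- stats::coef(stats::lm.fit(cbind(1, tt), div))[2]
  unname(slope / dt)
}

first_acf_zero <- function(x) {
  a <- acf(x, lag.max = min(length(x) - 2L, 200L), plot = FALSE)$acf[-1]
  z <- which(a <= 0)
  if (!length(z)) max(1L, round(length(x) / 10)) else z[1]
}

# anti-aliased decimation to about `target_hz`
decimate_series <- function(values, rate_hz, target_hz = 25) {
  q <- floor(rate_hz / target_hz)
  if (q <= 1L) return(list(values = values, rate_hz = rate_hz))
  if (sd(values) > 0) {
    bf <- signal::butter(4, 0.8 / q, type = "low")
    values <- signal::filtfilt(bf, values)
  }
  list(values = values[seq(1L, length(values), by = q)], rate_hz = rate_hz / q)
}

stream_magnitude <- function(stream) {
  v <- stream$values
  if (ncol(v) == 1L) as.numeric(v[, 1]) else sqrt(rowSums(v^2))
}

sliding_measure <- function(stream, fun, max_rate = 25) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (stream_duration(stream) < 30) {
    stop("stream must cover at least 30 s", call. = FALSE)
  }
  x <- stream_magnitude(stream)
  dec <- decimate_series(x, stream$rate_hz, max_rate)
  rate <- dec$rate_hz
  t0 <- stream$times[1]
  t1 <- stream$times[1] + length(dec$values) / rate
  starts <- sliding_starts(t0, t1)
  win_n <- round(30 * rate)
  vals <- vapply(starts, function(s) {
    i0 <- round((s - t0) * rate) + 1L
    idx <- i0:min(i0 + win_n - 1L, length(dec$values))
    fun(dec$values[idx], rate)
  }, numeric(1))
  list(starts = starts, values = vals, rate = rate)
}

#' Sliding-window sample entropy of a sensor stream
#'
#' Computes sample entropy (`m = 2`, `r = 0.2 x window SD`) over 30 s windows
#' slid at 1 s. Multichannel streams are reduced to their Euclidean magnitude
#' and high-rate streams are anti-alias decimated to 25 Hz first. A window
#' with zero variance is flagged `NA`.
#'
#' @param stream a [sensor_stream()] covering at least 30 s
#' @param max_rate decimation target rate in Hz (default 25)
#' @return a 1 Hz [derived_series()] of kind `"entropy"`
#' @export
sliding_entropy <- function(stream, max_rate = 25) {
  res <- sliding_measure(stream, function(w, rate) {
    s <- sd(w)
    # relative guard: anti-aliasing ripple on a constant window is not signal
    if (is.na(s) || s <= 1e-10 * (1 + abs(mean(w)))) return(NA_real_)
    sampen_cpp(w, 2L, 0.2 * s)
  }, max_rate)
  derived_series("entropy", stream$stream_id, 1, res$starts + 30, res$values)
}

#' Sliding-window largest Lyapunov exponent of a sensor stream
#'
#' Rosenstein largest-exponent estimate (embedding dimension 3, lag at the
#' first autocorrelation zero crossing, divergence fitted over a 0.5 s
#' horizon) per 30 s window slid at 1 s, after magnitude reduction and
#' decimation as in [sliding_entropy()].
#'
#' @inheritParams sliding_entropy
#' @return a 1 Hz [derived_series()] of kind `"lyapunov"` (units: 1/s)
#' @export
sliding_lyapunov <- function(stream, max_rate = 25) {
  res <- sliding_measure(stream, function(w, rate) {
    lyapunov_exponent(w, dt = 1 / rate)
  }, max_rate)
  derived_series("lyapunov", stream$stream_id, 1, res$starts + 30, res$values)
}
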