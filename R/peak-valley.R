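strict_extrema_idx <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  mid <- 2:(n - 1L)
  is_max <- x[mid] > x[mid - 1L] & x[mid] > x[mid + 1L]
  is_min <- x[mid] < x[mid - 1L] & x[mid] < x[mid + 1L]
  mid[is_max | is_min]
}

#' Basic summary statistics of a series
#'
#' The elementary feature operators: mean `m`, population standard deviation
#' `sigma`, minimum `eta`, maximum `zeta`, and the count `c` of strict local
#' extrema (which requires at least 3 points and is 0 otherwise).
#'
#' @param values numeric series (length >= 1)
#' @return named list `m`, `sigma`, `eta`, `zeta`, `c`
#' @examples
#' basic_stats(c(0, 1, 0, 1, 0))$c  # 3
#' @export
basic_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    return(list(m = NA_real_, sigma = NA_real_, eta = NA_real_,
                zeta = NA_real_, c = NA_real_))
  }
  list(m = mean(values), sigma = sd_pop(values),
       eta = min(values), zeta = max(values),
       c = length(strict_extrema_idx(values)))
}

#' Peak-valley summary of a series
#'
#' The peak-valley operator `v(series, threshold)` quantifies the significant
#' swings of a signal: (1) collect all strict local maxima and minima;
#' (2) min-max normalize the series to \[0, 1\]; (3) adopt an extremum iff its
#' normalized value falls outside the central band
#' `(0.5 - threshold/2, 0.5 + threshold/2)` -- larger thresholds keep only
#' the extrema closest to the signal envelope; (4) summarize the adopted
#' extrema on their raw scale by mean, population SD, count, minimum and
#' maximum. A constant series (normalization undefined) or a series with no
#' adopted extrema yields a count of 0 with the remaining summaries flagged
#' `NA`.
#'
#' @param values numeric series of length >= 3
#' @param threshold central-band width in \[0, 1)
#' @return an object of class `peak_valley_summary`: list with `mean`, `sd`,
#'   `count`, `min`, `max`, `threshold`
#' @examples
#' pv <- peak_valley(c(0, 1, 0, 1, 0), 0.25)
#' pv$count  # 3 adopted extrema
#' @export
peak_valley <- function(values, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  if (length(values) < 3L) {
    stop("`values` must contain at least 3 points", call. = FALSE)
  }
  empty <- structure(list(mean = NA_real_, sd = NA_real_, count = 0L,
                          min = NA_real_, max = NA_real_, threshold = threshold),
                     class = "peak_valley_summary")
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 3L) return(empty)
  rng <- range(x)
  if (rng[1] == rng[2]) return(empty)
  idx <- strict_extrema_idx(x)
  if (!length(idx)) return(empty)
  norm <- (x[idx] - rng[1]) / (rng[2] - rng[1])
  adopted <- x[idx][norm <= 0.5 - threshold / 2 | norm >= 0.5 + threshold / 2]
  if (!length(adopted)) return(empty)
  structure(list(mean = mean(adopted), sd = sd_pop(adopted),
                 count = length(adopted), min = min(adopted),
                 max = max(adopted), threshold = threshold),
            class = "peak_valley_summary")
}

#' @export
print.peak_valley_summary <- function(x, ...) {
  cat(sprintf("<peak_valley_summary> th=%g: count=%d mean=%.4g sd=%.4g [%.4g, %.4g]\n",
              x$threshold, x$count, x$mean, x$sd, x$min, x$max))
  invisible(x)
}
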