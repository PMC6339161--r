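#' @keywords internal
"_PACKAGE"

#' @useDynLib flowpick, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd var approx fft quantile rbinom
#'   pt cor predict median acf
#' @importFrom utils head tail write.csv read.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages consume seeds derived deterministically from one
#' master seed so that an entire simulated study is reproducible from a single
#' integer. Child seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param ... integer tags (e.g. subject index, session index, stream tag)
#' @return a single integer usable with [set.seed()]
#' @keywords internal
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 7919 + (as.numeric(t) %% 2147483647) + 1) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# population standard deviation (the feature battery uses the n-denominator)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

fmt_num <- function(x) {
  # canonical parameter formatting for feature names: no trailing zeros
  sub("\\.?0+$", "", sprintf("%.4f", x))
}
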