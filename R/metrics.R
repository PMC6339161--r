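#' Scale-normalized prediction error
#'
#' The per-sample discrepancy `|y_true - y_pred|` divided by a scale
#' constant, averaged over samples. With `method = "levels"` (default) the
#' constant is the number of answer levels of the questionnaire scale -- 7
#' for the pleasant and arousal axes of the circumplex grid, 5 for the
#' engagement scale -- so a one-point miss scores 1/7 (~0.14) and 1/5 (0.2)
#' respectively. `method = "range"` divides by the observed range
#' `max(y_true) - min(y_true)` instead.
#'
#' @param y_true questionnaire answers
#' @param y_pred predicted values
#' @param n_levels 7 or 5 (used by `method = "levels"`)
#' @param method `"levels"` (default) or `"range"`
#' @return mean normalized error (in \[0, 1\] when predictions are clipped
#'   to the scale)
#' @examples
#' normalized_error(3, 2, n_levels = 7)  # ~0.143
#' normalized_error(4, 3, n_levels = 5)  # 0.2
#' @export
normalized_error <- function(y_true, y_pred, n_levels = 7,
                             method = c("levels", "range")) {
  method <- match.arg(method)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  d <- abs(y_true - y_pred)
  if (method == "levels") {
    if (!n_levels %in% c(5, 7)) {
      stop("`n_levels` must be 7 (emotion axes) or 5 (engagement)", call. = FALSE)
    }
    mean(d) / n_levels
  } else {
    rng <- max(y_true) - min(y_true)
    if (rng <= 0) stop("`y_true` has zero range; use method = 'levels'", call. = FALSE)
    mean(d) / rng
  }
}

target_levels <- function(target) if (target == "engagement") 5 else 7
target_bounds <- function(target) if (target == "engagement") c(1, 5) else c(-3, 3)
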