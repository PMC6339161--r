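#' Dichotomize questionnaire responses
#'
#' Splits each affect/engagement scale into its two named groups: the
#' pleasant--unpleasant axis into `UPL` (value < 0) vs `PL` (otherwise), the
#' arousal--sleepy axis into `SE` (value < 0) vs `AR` (otherwise), and
#' engagement into `BR` (boredom, value < 3) vs `CR` (concentration,
#' otherwise). Boundary values (0 and 3) therefore go to `PL`/`AR`/`CR`.
#'
#' @param q a data.frame (or list) with columns `pleasant` (-3..3),
#'   `arousal` (-3..3) and `engagement` (1..5)
#' @return data.frame with factor columns `pleasant_group`, `arousal_group`,
#'   `engagement_group`
#' @examples
#' dichotomize(data.frame(pleasant = 0, arousal = -1, engagement = 3))
#' @export
dichotomize <- function(q) {
  q <- as.data.frame(q)
  if (any(q$pleasant < -3 | q$pleasant > 3) ||
      any(q$arousal < -3 | q$arousal > 3) ||
      any(q$engagement < 1 | q$engagement > 5)) {
    stop("questionnaire values out of scale bounds", call. = FALSE)
  }
  data.frame(
    pleasant_group = factor(ifelse(q$pleasant < 0, "UPL", "PL"), c("UPL", "PL")),
    arousal_group = factor(ifelse(q$arousal < 0, "SE", "AR"), c("SE", "AR")),
    engagement_group = factor(ifelse(q$engagement < 3, "BR", "CR"), c("BR", "CR"))
  )
}

#' Brunner-Munzel rank test
#'
#' Nonparametric test of the relative effect `p = P(X < Y) + 0.5 P(X = Y)`
#' against the null `p = 0.5`, robust to unequal variances and ties
#' (mid-ranks). The statistic is referred to a t distribution with
#' Satterthwaite-approximated degrees of freedom (standard normal when
#' `df >= 1000`); the p-value is two-sided.
#'
#' Complete separation (zero rank variance in both groups but different mean
#' ranks) yields an infinite statistic with `p_value = 0`; two degenerate
#' groups with equal mean ranks (e.g. both constant and tied) make the test
#' undefined and raise an error of class `flowpick_degenerate_test`.
#'
#' @param x,y numeric samples (each of length >= 2)
#' @return object of class `bm_test`: list with `statistic`, `df`, `p_value`,
#'   `p_hat`, `n_x`, `n_y`
#' @examples
#' bm <- brunner_munzel(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' bm$p_hat
#' @export
brunner_munzel <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("both samples must contain at least 2 finite values", call. = FALSE)
  }
  N <- n1 + n2
  R <- rank(c(x, y), ties.method = "average")
  R1 <- R[seq_len(n1)]
  R2 <- R[n1 + seq_len(n2)]
  r1 <- rank(x, ties.method = "average")
  r2 <- rank(y, ties.method = "average")
  m1 <- mean(R1)
  m2 <- mean(R2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((R1 - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((R2 - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled <= 0) {
    if (m1 == m2) {
      stop(structure(
        class = c("flowpick_degenerate_test", "error", "condition"),
        list(message = "Brunner-Munzel test undefined: zero rank variance in both groups",
             call = sys.call())))
    }
    statistic <- sign(m2 - m1) * Inf
    return(structure(list(statistic = statistic, df = NA_real_, p_value = 0,
                          p_hat = p_hat, n_x = n1, n_y = n2),
                     class = "bm_test"))
  }
  statistic <- (n1 * n2 * (m2 - m1)) / (N * sqrt(pooled))
  df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p_value <- if (is.finite(df) && df < 1000) {
    2 * pt(-abs(statistic), df)
  } else {
    2 * stats::pnorm(-abs(statistic))
  }
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 p_hat = p_hat, n_x = n1, n_y = n2),
            class = "bm_test")
}

#' @export
print.bm_test <- function(x, ...) {
  cat(sprintf("<bm_test> statistic=%.4g df=%.3g p=%.4g p_hat=%.4g (n=%d,%d)\n",
              x$statistic, x$df, x$p_value, x$p_hat, x$n_x, x$n_y))
  invisible(x)
}

#' Screen features with the Brunner-Munzel test
#'
#' Runs one Brunner-Munzel test per feature column between the two groups of
#' the dichotomized target and selects features with `p < alpha`. No
#' multiplicity adjustment is applied by default (set `adjust = "BH"` for an
#' optional Benjamini-Hochberg variant). Features whose test is undefined
#' (e.g. constant columns) are skipped and reported with `NA` statistics.
#'
#' @param features numeric matrix (sessions x features) or a
#'   [build_feature_matrix()] result
#' @param labels a [dichotomize()] result (or a data.frame of questionnaire
#'   responses, which will be dichotomized)
#' @param target `"pleasant"`, `"arousal"` or `"engagement"`
#' @param alpha rejection region (default 0.01)
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame of class `selection_result`: one row per feature with
#'   `feature`, `statistic`, `df`, `p_value`, `p_hat`, `mean_neg`,
#'   `mean_pos`, `selected`; attribute `target` and `groups`
#' @export
select_features <- function(features, labels,
                            target = c("pleasant", "arousal", "engagement"),
                            alpha = 0.01, adjust = c("none", "BH")) {
  target <- match.arg(target)
  adjust <- match.arg(adjust)
  if (inherits(features, "feature_matrix")) {
    if (missing(labels)) labels <- dichotomize(features$meta)
    features <- features$X
  }
  if (!all(c("pleasant_group", "arousal_group", "engagement_group") %in% names(labels))) {
    labels <- dichotomize(labels)
  }
  grp <- labels[[paste0(target, "_group")]]
  lev <- levels(grp)
  neg <- grp == lev[1]
  pos <- grp == lev[2]
  if (!any(neg) || !any(pos)) {
    stop(sprintf("group '%s' is empty; cannot screen features",
                 lev[c(!any(neg), !any(pos))][1]), call. = FALSE)
  }
  if (sum(neg) < 10 || sum(pos) < 10) {
    warning(sprintf("small group sizes (%s=%d, %s=%d): screening is low-powered",
                    lev[1], sum(neg), lev[2], sum(pos)), call. = FALSE)
  }
  p <- ncol(features)
  res <- data.frame(
    feature = colnames(features), statistic = NA_real_, df = NA_real_,
    p_value = NA_real_, p_hat = NA_real_, mean_neg = NA_real_,
    mean_pos = NA_real_, selected = FALSE, stringsAsFactors = FALSE
  )
  skipped <- character(0)
  for (j in seq_len(p)) {
    xn <- features[neg, j]
    xp <- features[pos, j]
    bm <- tryCatch(brunner_munzel(xn, xp), error = function(e) e)
    if (inherits(bm, "error")) {
      skipped <- c(skipped, colnames(features)[j])
      next
    }
    res$statistic[j] <- bm$statistic
    res$df[j] <- bm$df
    res$p_value[j] <- bm$p_value
    res$p_hat[j] <- bm$p_hat
    res$mean_neg[j] <- mean(xn, na.rm = TRUE)
    res$mean_pos[j] <- mean(xp, na.rm = TRUE)
  }
  pv <- res$p_value
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  res$selected <- !is.na(pv) & pv < alpha
  if (length(skipped)) {
    attr(res, "skipped") <- skipped
    message(sprintf("select_features: skipped %d feature(s) with undefined tests",
                    length(skipped)))
  }
  attr(res, "target") <- target
  attr(res, "groups") <- lev
  attr(res, "alpha") <- alpha
  class(res) <- c("selection_result", "data.frame")
  res
}
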