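## Cross-validation designs: leave-one-subject-out for the generalized model
## and leave-one-session-out within a subject for the personalized model.
## Every fold re-runs feature screening on its training rows (leak-free
## default), z-scores on the training rows only, trains the network and
## scores the held-out rows with the scale-normalized error.

impute_median <- function(Xtr, Xte) {
  med <- apply(Xtr, 2, function(v) median(v, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(Xtr))) {
    Xtr[!is.finite(Xtr[, j]), j] <- med[j]
    Xte[!is.finite(Xte[, j]), j] <- med[j]
  }
  list(train = Xtr, test = Xte)
}

fold_fit_predict <- function(X, meta, train_idx, test_idx, target, spec,
                             alpha, selection, fold_seed) {
  ytr <- meta[[target]][train_idx]
  sel_names <- colnames(X)
  if (selection == "per_fold") {
    sel <- tryCatch(
      suppressWarnings(suppressMessages(
        select_features(X[train_idx, , drop = FALSE],
                        dichotomize(meta[train_idx, , drop = FALSE]),
                        target, alpha = alpha))),
      error = function(e) NULL)
    if (!is.null(sel) && any(sel$selected)) {
      sel_names <- sel$feature[sel$selected]
    } else {
      warning("fold selected no features; falling back to the full battery",
              call. = FALSE)
    }
  }
  Xi <- impute_median(X[train_idx, sel_names, drop = FALSE],
                      X[test_idx, sel_names, drop = FALSE])
  spec_fold <- spec
  spec_fold$seed <- fold_seed
  model <- train_regressor(Xi$train, ytr, spec_fold, bounds = target_bounds(target))
  list(pred = predict(model, Xi$test), model = model, n_selected = length(sel_names))
}

#' Leave-one-subject-out cross-validation (generalized model)
#'
#' One fold per subject: the network is trained on every other subject's
#' sessions (with Brunner-Munzel screening re-run on the training rows by
#' default) and evaluated on all sessions of the held-out subject with the
#' scale-normalized error.
#'
#' @param features a `feature_matrix` ([build_feature_matrix()] /
#'   [simulate_feature_matrix()])
#' @param target `"pleasant"`, `"arousal"` or `"engagement"`
#' @param spec a [network_spec()]
#' @param alpha screening rejection region (default 0.01)
#' @param selection `"per_fold"` (leak-free default) or `"global"`
#'   (screening once on all rows before cross-validation)
#' @param error_method passed to [normalized_error()]
#' @param seed master seed for fold-level training randomness
#' @return object of class `cv_result` with per-fold and mean errors
#' @export
loso_cv <- function(features, target = c("pleasant", "arousal", "engagement"),
                    spec = network_spec(), alpha = 0.01,
                    selection = c("per_fold", "global"),
                    error_method = "levels", seed = 1L) {
  target <- match.arg(target)
  selection <- match.arg(selection)
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$X
  meta <- features$meta
  subjects <- sort(unique(meta$subject))
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects", call. = FALSE)
  if (selection == "global") {
    sel <- suppressWarnings(suppressMessages(
      select_features(X, dichotomize(meta), target, alpha = alpha)))
    if (any(sel$selected)) X <- X[, sel$feature[sel$selected], drop = FALSE]
  }
  n_levels <- target_levels(target)
  errs <- numeric(length(subjects))
  n_sel <- integer(length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_idx <- which(meta$subject == s)
    train_idx <- which(meta$subject != s)
    fit <- fold_fit_predict(X, meta, train_idx, test_idx, target, spec,
                            alpha, selection, derive_seed(seed, 801L, k))
    errs[k] <- normalized_error(meta[[target]][test_idx], fit$pred,
                                n_levels, error_method)
    n_sel[k] <- fit$n_selected
  }
  structure(list(design = "loso", target = target,
                 device_group = features$device_group,
                 fold_ids = subjects, fold_errors = errs,
                 mean_error = mean(errs), n_selected = n_sel,
                 n_folds = length(subjects)),
            class = "cv_result")
}

#' Leave-one-session-out cross-validation (personalized model)
#'
#' Within each subject, one fold per session: the network is trained on the
#' subject's other sessions and evaluated on the held-out one. With multiple
#' subjects the per-session errors are averaged within subject and then
#' across subjects.
#'
#' @inheritParams loso_cv
#' @param subjects subjects to evaluate (default: all in `features`)
#' @return object of class `cv_result`; `fold_errors` holds per-subject mean
#'   errors, `session_errors` the full per-(subject, session) breakdown
#' @export
personalized_cv <- function(features, target = c("pleasant", "arousal", "engagement"),
                            spec = network_spec(), alpha = 0.01,
                            selection = c("per_fold", "global"),
                            error_method = "levels", seed = 1L, subjects = NULL) {
  target <- match.arg(target)
  selection <- match.arg(selection)
  stopifnot(inherits(features, "feature_matrix"))
  meta <- features$meta
  subjects <- subjects %||% sort(unique(meta$subject))
  n_levels <- target_levels(target)
  subj_err <- numeric(length(subjects))
  detail <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    rows <- which(meta$subject == s)
    if (length(rows) < 4L) stop("personalized CV needs at least 4 sessions per subject",
                                call. = FALSE)
    Xs <- features$X[rows, , drop = FALSE]
    ms <- meta[rows, , drop = FALSE]
    errs <- numeric(length(rows))
    for (i in seq_along(rows)) {
      fit <- fold_fit_predict(Xs, ms, setdiff(seq_along(rows), i), i, target,
                              spec, alpha, selection,
                              derive_seed(seed, 802L, k, i))
      errs[i] <- normalized_error(ms[[target]][i], fit$pred, n_levels, error_method)
    }
    subj_err[k] <- mean(errs)
    detail[[as.character(s)]] <- errs
  }
  structure(list(design = "per-subject-LOO", target = target,
                 device_group = features$device_group,
                 fold_ids = subjects, fold_errors = subj_err,
                 session_errors = detail,
                 mean_error = mean(subj_err), n_folds = length(subjects)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s / %s: mean normalized error %.4f over %d folds\n",
              x$design, x$target, x$device_group, x$mean_error, x$n_folds))
  invisible(x)
}
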