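#' Assemble a full run configuration
#'
#' Bundles everything one end-to-end analysis needs: the generator
#' configuration, the network specification, the screening level, the
#' cross-validation designs, device groups and targets to evaluate, and the
#' master seed. The resolved configuration is hashed so every output file of
#' a run can be traced to the exact configuration that produced it.
#'
#' @param cfg an [effect_config()]
#' @param spec a [network_spec()]
#' @param alpha screening rejection region
#' @param targets regression targets to evaluate
#' @param groups device groups to evaluate
#' @param designs `"loso"` and/or `"personalized"`
#' @param selection `"per_fold"` (leak-free) or `"global"` screening
#' @param error_method `"levels"` or `"range"` (see [normalized_error()])
#' @param seed master seed
#' @return an object of class `run_config`
#' @export
run_config <- function(cfg = effect_config(), spec = network_spec(),
                       alpha = 0.01,
                       targets = c("pleasant", "arousal", "engagement"),
                       groups = c("pulse", "eye", "motion"),
                       designs = c("loso", "personalized"),
                       selection = c("per_fold", "global"),
                       error_method = c("levels", "range"), seed = 1L) {
  selection <- match.arg(selection)
  error_method <- match.arg(error_method)
  rc <- structure(list(cfg = cfg, spec = spec, alpha = alpha,
                       targets = targets, groups = groups, designs = designs,
                       selection = selection, error_method = error_method,
                       seed = as.integer(seed)),
                  class = "run_config")
  rc$config_hash <- config_hash(rc)
  rc
}

# polynomial rolling hash over the serialized configuration
config_hash <- function(x) {
  x$config_hash <- NULL
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])  # skip header
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Run the full pipeline: simulate, extract, screen, train, report
#'
#' Executes the five stages in order for every requested combination of
#' device group, target and cross-validation design: (1) simulate the study
#' and extract per-session feature matrices; (2) screen features with the
#' Brunner-Munzel test (reported globally; re-run inside each training fold
#' when `selection = "per_fold"`); (3) train and cross-validate the network;
#' (4) aggregate a summary of mean normalized errors; (5) optionally write
#' all artifacts (features, selections, per-fold errors, summary, run
#' metadata with the config hash) as CSV/JSON under `out_dir`. A run is fully
#' reproducible from its configuration and seed.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory; refuses to mix outputs of
#'   different configurations unless `overwrite = TRUE`
#' @param overwrite allow overwriting an `out_dir` holding a different run
#' @param progress print stage progress
#' @return list of class `run_bundle`: `summary` (one row per design x
#'   target x group), `cv_results`, `selections`, `importance` (one ranked
#'   table per target x group), `features`, `config`
#' @export
run_all <- function(config = run_config(), out_dir = NULL, overwrite = FALSE,
                    progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message(sprintf(...))
  if (!is.null(out_dir)) {
    meta_path <- file.path(out_dir, "run_meta.json")
    if (file.exists(meta_path)) {
      prev <- jsonlite::read_json(meta_path)
      if (!identical(prev$config_hash, config$config_hash) && !overwrite) {
        stop("out_dir holds outputs of a different configuration (hash ",
             prev$config_hash, "); use overwrite = TRUE", call. = FALSE)
      }
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  t_start <- Sys.time()
  ## stage 1: simulate + extract
  say("[1/5] simulating %d x %d sessions and extracting features",
      config$cfg$n_subjects, config$cfg$n_sessions)
  features <- list()
  for (g in config$groups) {
    features[[g]] <- simulate_feature_matrix(config$cfg, config$seed, g)
  }
  ## stage 2: global screening report
  say("[2/5] Brunner-Munzel screening (alpha = %g)", config$alpha)
  selections <- list()
  for (g in config$groups) {
    for (tg in config$targets) {
      key <- paste(tg, g, sep = ".")
      selections[[key]] <- suppressWarnings(suppressMessages(
        select_features(features[[g]], target = tg, alpha = config$alpha)))
    }
  }
  ## stage 3-4: cross-validated training
  say("[3/5] training and cross-validating")
  cv_results <- list()
  summary_rows <- list()
  for (design in config$designs) {
    for (g in config$groups) {
      for (tg in config$targets) {
        key <- paste(design, tg, g, sep = ".")
        cv <- if (design == "loso") {
          loso_cv(features[[g]], tg, config$spec, config$alpha,
                  config$selection, config$error_method,
                  seed = derive_seed(config$seed, 901L))
        } else {
          personalized_cv(features[[g]], tg, config$spec, config$alpha,
                          config$selection, config$error_method,
                          seed = derive_seed(config$seed, 902L))
        }
        cv_results[[key]] <- cv
        summary_rows[[key]] <- data.frame(
          design = design, target = tg, device_group = g,
          mean_error = cv$mean_error, n_folds = cv$n_folds,
          stringsAsFactors = FALSE
        )
        say("      %s: %.4f", key, cv$mean_error)
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  ## stage 5: report, incl. variable-importance tables from a final model
  ## per (target, group) fitted on the screened full data
  say("[5/5] ranking variable importance and writing report")
  importance <- list()
  for (g in config$groups) {
    for (tg in config$targets) {
      key <- paste(tg, g, sep = ".")
      sel <- selections[[key]]
      keep <- if (any(sel$selected)) sel$feature[sel$selected] else sel$feature
      Xi <- impute_median(features[[g]]$X[, keep, drop = FALSE],
                          features[[g]]$X[, keep, drop = FALSE])$train
      spec_imp <- config$spec
      spec_imp$seed <- derive_seed(config$seed, 903L)
      model <- train_regressor(Xi, features[[g]]$meta[[tg]], spec_imp,
                               bounds = target_bounds(tg))
      importance[[key]] <- variable_importance(model)
    }
  }
  bundle <- structure(list(summary = summary, cv_results = cv_results,
                           selections = selections, importance = importance,
                           features = features, config = config,
                           elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                           units = "secs"))),
                      class = "run_bundle")
  if (!is.null(out_dir)) write_run_bundle(bundle, out_dir)
  bundle
}

write_run_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- bundle$config$config_hash
  summary <- bundle$summary
  summary$config_hash <- hash
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  for (g in names(bundle$features)) {
    fm <- bundle$features[[g]]
    df <- cbind(fm$meta, as.data.frame(fm$X, check.names = FALSE))
    write.csv(df, file.path(out_dir, sprintf("features_%s.csv", g)),
              row.names = FALSE)
  }
  for (key in names(bundle$selections)) {
    write.csv(as.data.frame(bundle$selections[[key]]),
              file.path(out_dir, sprintf("selection_%s.csv", key)),
              row.names = FALSE)
  }
  for (key in names(bundle$importance)) {
    write.csv(as.data.frame(bundle$importance[[key]]),
              file.path(out_dir, sprintf("importance_%s.csv", key)),
              row.names = FALSE)
  }
  folds <- do.call(rbind, lapply(names(bundle$cv_results), function(key) {
    cv <- bundle$cv_results[[key]]
    data.frame(design = cv$design, target = cv$target,
               device_group = cv$device_group, fold = cv$fold_ids,
               error = cv$fold_errors, stringsAsFactors = FALSE)
  }))
  folds$config_hash <- hash
  write.csv(folds, file.path(out_dir, "cv_results.csv"), row.names = FALSE)
  meta <- list(config_hash = hash, seed = bundle$config$seed,
               n_subjects = bundle$config$cfg$n_subjects,
               n_sessions = bundle$config$cfg$n_sessions,
               alpha = bundle$config$alpha,
               selection = bundle$config$selection,
               error_method = bundle$config$error_method,
               elapsed_s = bundle$elapsed_s,
               algorithms = list(
                 entropy = "sample entropy, m = 2, r = 0.2 x window SD",
                 lyapunov = "Rosenstein largest exponent, dim 3, 0.5 s fit",
                 heart_rate = "instantaneous 60000/RR",
                 psd = "Hann periodogram, Nyquist/20 bins"
               ))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> hash %s, %.1f s\n", x$config$config_hash, x$elapsed_s))
  print(x$summary)
  invisible(x)
}
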