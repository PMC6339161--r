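#' Generate a complete synthetic study dataset
#'
#' Draws latent states for every (subject, session), then synthesizes all
#' sensor streams, an order sheet, a working time in (0, 60\] seconds, a
#' Poisson human-error count (rate falling with pleasantness, rising with
#' sheet complexity) and a questionnaire response equal to the discretized
#' latent state. A 9-item flow-state-scale response per (subject, period) is
#' emitted alongside. Identical `(cfg, seed)` give identical datasets.
#'
#' @param cfg an [effect_config()]
#' @param seed master integer seed
#' @param streams generate the raw sensor streams (set `FALSE` for fast
#'   design-level simulations that only need sheets, times and questionnaires)
#' @param out_dir optional directory: when given, the dataset is also written
#'   to disk via [write_dataset()]
#' @return an object of class `picking_dataset`: list with `sessions` (list of
#'   `picking_session`), `states` (the [sample_latent_states()] table),
#'   `flow_scale`, `cfg`, `seed`
#' @examples
#' ds <- generate_dataset(effect_config(2, 2), seed = 1, streams = FALSE)
#' length(ds$sessions)  # 4
#' @export
generate_dataset <- function(cfg = effect_config(), seed = 1L, streams = TRUE,
                             out_dir = NULL) {
  stopifnot(inherits(cfg, "effect_config"))
  states <- sample_latent_states(cfg$n_subjects, cfg$n_sessions, cfg, seed)
  subj_amp <- with_seed(derive_seed(seed, 301L),
                        exp(rnorm(cfg$n_subjects, 0, cfg$subject_amp_sd)))
  sessions <- vector("list", nrow(states))
  devices <- if (streams) c("pulse", "motion", "eye") else character(0)
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    sessions[[i]] <- synth_session(st, cfg, seed, subj_amp[st$subject], devices)
  }
  flow_scale <- flow_scale_responses(states, seed)
  ds <- structure(list(sessions = sessions, states = states,
                       flow_scale = flow_scale, cfg = cfg, seed = seed),
                  class = "picking_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

# synthesize one session; `devices` selects which stream synthesizers run
# (seed derivations are per-device, so a subset reproduces exactly the same
# streams as the full set)
synth_session <- function(st, cfg, master_seed, subj_amp_value,
                          devices = c("pulse", "motion", "eye")) {
  sess_seed <- derive_seed(master_seed, 311L, st$subject, st$session)
  with_seed(sess_seed, {
    sheet <- synthesize_order_sheets(st$complexity, seed = sess_seed)
    wt <- clamp(rnorm(1,
                      cfg$working_time_mean_s -
                        cfg$working_time_skill_slope * log(st$subject_skill) -
                        3 * cfg$strength * (st$flow - 0.5),
                      cfg$working_time_sd_s),
                cfg$working_time_min_s, cfg$working_time_max_s)
    err_rate <- cfg$error_rate_base *
      exp(-cfg$error_pleasant_suppression * st$pleasant +
            cfg$error_complex_gain * (st$complexity == "complex"))
    errors <- rpois(1L, err_rate)
    sess <- list(
      subject = st$subject, session = st$session, period = st$period,
      complexity = st$complexity, working_time_s = wt,
      human_errors = errors, order_sheet = sheet,
      questionnaire = list(pleasant = st$pleasant, arousal = st$arousal,
                           engagement = st$engagement,
                           difficulty = st$subjective_difficulty)
    )
    strm <- list()
    if ("pulse" %in% devices) {
      strm[["p^pulse"]] <- synthesize_pulse_wave(st, wt, cfg,
                                                 seed = derive_seed(sess_seed, 1L))
    }
    if ("motion" %in% devices) {
      strm <- c(strm, synthesize_motion(st, wt, cfg, seed = derive_seed(sess_seed, 2L),
                                        subject_factor = subj_amp_value))
    }
    if ("eye" %in% devices) {
      eye <- synthesize_eye(st, wt, cfg, seed = derive_seed(sess_seed, 3L))
      strm <- c(strm, eye$streams)
      sess$blink_count <- eye$blink_count
      sess$saccade_count <- eye$saccade_count
    }
    if (length(strm)) sess$streams <- strm
    class(sess) <- "picking_session"
    sess
  })
}

# 9-item flow state scale (7-point Likert), one response per subject x period:
# noisy readout of the subject's mean flow in that period
flow_scale_responses <- function(states, seed) {
  with_seed(derive_seed(seed, 321L), {
    agg <- stats::aggregate(flow ~ subject + period, data = states, FUN = mean)
    qs <- t(vapply(seq_len(nrow(agg)), function(i) {
      as.integer(clamp(round(1 + agg$flow[i] * 6 + rnorm(9, 0, 0.8)), 1L, 7L))
    }, integer(9)))
    colnames(qs) <- paste0("q", 1:9)
    cbind(agg[, c("subject", "period")], as.data.frame(qs))
  })
}

#' @export
print.picking_dataset <- function(x, ...) {
  cat(sprintf("<picking_dataset> %d subjects x %d sessions (%d total), seed %d\n",
              x$cfg$n_subjects, x$cfg$n_sessions, length(x$sessions), x$seed))
  cat(sprintf("  streams per session: %s\n",
              if (is.null(x$sessions[[1]]$streams)) "none (design only)"
              else length(x$sessions[[1]]$streams)))
  invisible(x)
}

#' @export
print.picking_session <- function(x, ...) {
  cat(sprintf("<picking_session> subject %d session %d (%s, period %d): t=%.1fs, errors=%d\n",
              x$subject, x$session, x$complexity, x$period,
              x$working_time_s, x$human_errors))
  invisible(x)
}

session_label <- function(sess) sprintf("subj%02d_sess%02d", sess$subject, sess$session)

#' Write a dataset to disk as CSV streams plus a JSON manifest
#'
#' Each stream goes to `<dir>/<subjNN_sessNN>/<stream>.csv` with header
#' `time_s,v1[,v2,v3]`; a `manifest.json` records per-session metadata
#' (period, working time, human errors, questionnaire, order sheet, declared
#' rates and stream file paths).
#'
#' @param dataset a [generate_dataset()] result (with streams)
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "picking_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_subjects = dataset$cfg$n_subjects, n_sessions = dataset$cfg$n_sessions,
    seed = dataset$seed, sessions = list()
  )
  for (sess in dataset$sessions) {
    lab <- session_label(sess)
    entry <- list(
      subject = sess$subject, session = sess$session, period = sess$period,
      complexity = sess$complexity,
      working_time_s = round(sess$working_time_s, 6),
      human_errors = sess$human_errors,
      questionnaire = sess$questionnaire,
      order_sheet = list(
        complexity_class = sess$order_sheet$complexity_class,
        lists = lapply(sess$order_sheet$lists, function(df) {
          list(area = df$area, item = df$item, count = df$count)
        })
      ),
      blink_count = sess$blink_count, saccade_count = sess$saccade_count,
      streams = list()
    )
    if (!is.null(sess$streams)) {
      sdir <- file.path(dir, lab)
      dir.create(sdir, showWarnings = FALSE)
      for (stream in sess$streams) {
        fname <- paste0(gsub("[\\^]", "_", stream$stream_id), ".csv")
        df <- data.frame(time_s = stream$times)
        v <- as.matrix(stream$values)
        colnames(v) <- paste0("v", seq_len(ncol(v)))
        df <- cbind(df, v)
        write.csv(df, file.path(sdir, fname), row.names = FALSE)
        entry$streams[[stream$stream_id]] <- list(
          path = file.path(lab, fname), rate_hz = stream$rate_hz,
          channels = ncol(stream$values)
        )
      }
    }
    manifest$sessions[[lab]] <- entry
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a dataset manifest and load its sessions
#'
#' Checks that every referenced stream file exists, that declared sampling
#' rates are positive and consistent with the stored time axes, and that
#' questionnaire responses lie on their scales (pleasant/arousal in -3..3,
#' engagement in 1..5, difficulty in -2..2). All violations are collected and
#' reported together.
#'
#' @param path path to a `manifest.json` written by [write_dataset()]
#' @param load_streams read the stream CSVs back into memory (default `TRUE`)
#' @return a list of validated `picking_session` objects
#' @export
validate_manifest <- function(path, load_streams = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  dir <- dirname(path)
  manifest <- jsonlite::read_json(path)
  problems <- character()
  sessions <- list()
  for (lab in names(manifest$sessions)) {
    entry <- manifest$sessions[[lab]]
    q <- entry$questionnaire
    chk <- function(ok, msg) {
      if (!isTRUE(ok)) problems <<- c(problems, sprintf("%s: %s", lab, msg))
    }
    chk(q$pleasant >= -3 && q$pleasant <= 3, sprintf("pleasant=%s out of [-3,3]", q$pleasant))
    chk(q$arousal >= -3 && q$arousal <= 3, sprintf("arousal=%s out of [-3,3]", q$arousal))
    chk(q$engagement >= 1 && q$engagement <= 5, sprintf("engagement=%s out of [1,5]", q$engagement))
    chk(q$difficulty >= -2 && q$difficulty <= 2, sprintf("difficulty=%s out of [-2,2]", q$difficulty))
    chk(entry$working_time_s > 0 && entry$working_time_s <= 60,
        sprintf("working_time_s=%s out of (0,60]", entry$working_time_s))
    sess <- list(
      subject = entry$subject, session = entry$session, period = entry$period,
      complexity = entry$complexity, working_time_s = entry$working_time_s,
      human_errors = entry$human_errors,
      questionnaire = q,
      order_sheet = structure(
        list(complexity_class = entry$order_sheet$complexity_class,
             lists = lapply(entry$order_sheet$lists, function(l) {
               data.frame(area = unlist(l$area), item = unlist(l$item),
                          count = unlist(l$count), stringsAsFactors = FALSE)
             })),
        class = "order_sheet"),
      blink_count = entry$blink_count, saccade_count = entry$saccade_count
    )
    if (length(entry$streams)) {
      sess$streams <- list()
      for (sid in names(entry$streams)) {
        sinfo <- entry$streams[[sid]]
        fpath <- file.path(dir, sinfo$path)
        if (!file.exists(fpath)) {
          problems <- c(problems, sprintf("%s: missing stream file %s", lab, sinfo$path))
          next
        }
        if (sinfo$rate_hz <= 0) {
          problems <- c(problems, sprintf("%s: non-positive rate for %s", lab, sid))
          next
        }
        if (load_streams) {
          df <- read.csv(fpath)
          sess$streams[[sid]] <- sensor_stream(sid, sinfo$rate_hz, df$time_s,
                                               as.matrix(df[, -1, drop = FALSE]))
        }
      }
    }
    class(sess) <- "picking_session"
    sessions[[lab]] <- sess
  }
  if (length(problems)) {
    stop("manifest validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  sessions
}
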