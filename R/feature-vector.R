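## The per-session feature battery.
##
## Feature names follow the canonical stat(transform(stream)[, param])
## grammar: m/sigma/eta/zeta/c are the basic stats, f(X, freq) the binned
## PSD value, v(X, th) the peak-valley operator (summarized by the five basic
## stats), e(X)/lyap(X) the sliding entropy / largest Lyapunov exponent
## series, and p^VLF etc. the sliding HRV band powers.

pv_thresholds <- c(0.1, 0.15, 0.25, 0.3, 0.5, 0.75, 0.9)

# full battery for one named series: 5 basic stats + 10 PSD-grid values
# (multiples of Nyquist/10) + 5 peak-valley summaries x 7 thresholds
series_battery <- function(name, values, rate_hz) {
  out <- numeric(0)
  bs <- basic_stats(values)
  out[sprintf("m(%s)", name)] <- bs$m
  out[sprintf("sigma(%s)", name)] <- bs$sigma
  out[sprintf("eta(%s)", name)] <- bs$eta
  out[sprintf("zeta(%s)", name)] <- bs$zeta
  out[sprintf("c(%s)", name)] <- bs$c
  freqs <- (1:10) * rate_hz / 20
  bins <- psd_bins(values[is.finite(values)], rate_hz)
  for (fr in freqs) {
    k <- round(fr / (rate_hz / 40)) + 1L
    out[sprintf("f(%s,%s)", name, fmt_num(fr))] <- bins$density[k]
  }
  n_ok <- sum(is.finite(values))
  for (th in pv_thresholds) {
    pv_name <- sprintf("v(%s,%s)", name, fmt_num(th))
    if (n_ok >= 3L) {
      pv <- peak_valley(values, th)
      out[sprintf("m(%s)", pv_name)] <- pv$mean
      out[sprintf("sigma(%s)", pv_name)] <- pv$sd
      out[sprintf("c(%s)", pv_name)] <- pv$count
      out[sprintf("eta(%s)", pv_name)] <- pv$min
      out[sprintf("zeta(%s)", pv_name)] <- pv$max
    } else {
      out[sprintf("m(%s)", pv_name)] <- NA_real_
      out[sprintf("sigma(%s)", pv_name)] <- NA_real_
      out[sprintf("c(%s)", pv_name)] <- NA_real_
      out[sprintf("eta(%s)", pv_name)] <- NA_real_
      out[sprintf("zeta(%s)", pv_name)] <- NA_real_
    }
  }
  out
}

require_streams <- function(session, ids) {
  missing <- setdiff(ids, names(session$streams))
  if (length(missing)) {
    stop("missing stream(s) for this device group: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

axis_series_name <- function(stream_id, axis) {
  # "r^BT" + "z" -> "r_z^BT"
  parts <- strsplit(stream_id, "^", fixed = TRUE)[[1]]
  sprintf("%s_%s^%s", parts[1], axis, parts[2])
}

#' Build the per-session feature vector of one device group
#'
#' Applies the full feature battery to the streams of a device group and
#' appends the nine task-complexity components:
#'
#' * `pulse`: sliding HRV band powers `p^VLF`, `p^LF`, `p^HF`, `p^TP`,
#'   the 1 Hz RR and heart-rate series `p^RR`, `p^HR`, and the sliding sample
#'   entropy / Lyapunov series of the chest IMU, `e(a^S3)`, `lyap(a^S3)`,
#'   `e(g^S3)`, `lyap(g^S3)`.
#' * `eye`: each axis of eye movement (`u_x^3D`, ...), point of view
#'   (`u_x^2D`, `u_y^2D`), pupil diameter `u^PD`, head IMU axes (`a_x^HD`,
#'   ..., `g_z^HD`), plus the blink and saccade counts `m(u^BK)`, `m(u^SC)`.
#' * `motion`: each axis of the eleven joint rotation streams (`r_x^LH` ...
#'   `r_z^HD`) plus per-joint mean-angle summaries (`m(r^LA)` etc.).
#'
#' Each series contributes its basic stats, the PSD-grid values at multiples
#' of Nyquist/10, and peak-valley summaries at thresholds
#' \{0.1, 0.15, 0.25, 0.3, 0.5, 0.75, 0.9\}. Extraction is deterministic:
#' repeated calls on the same session are identical.
#'
#' @param session a `picking_session` (with streams)
#' @param device_group `"pulse"`, `"eye"` or `"motion"`
#' @return named numeric vector with attribute `device_group`; values may be
#'   `NA` where a summary is undefined (flagged missing)
#' @export
build_feature_vector <- function(session, device_group = c("pulse", "eye", "motion")) {
  device_group <- match.arg(device_group)
  out <- numeric(0)
  if (device_group == "pulse") {
    require_streams(session, c("p^pulse", "a^S3", "g^S3"))
    rr <- detect_rr(session$streams[["p^pulse"]])
    for (band in c("VLF", "LF", "HF", "TP")) {
      bs <- hrv_band_series(rr, band)
      out <- c(out, series_battery(paste0("p^", band), bs$values, 1))
    }
    rs <- rr_rate_series(rr)
    out <- c(out, series_battery("p^RR", rs$RR$values, 1))
    out <- c(out, series_battery("p^HR", rs$HR$values, 1))
    for (sid in c("a^S3", "g^S3")) {
      ent <- sliding_entropy(session$streams[[sid]])
      lya <- sliding_lyapunov(session$streams[[sid]])
      out <- c(out, series_battery(sprintf("e(%s)", sid), ent$values, 1))
      out <- c(out, series_battery(sprintf("lyap(%s)", sid), lya$values, 1))
    }
  } else if (device_group == "eye") {
    require_streams(session, c("u^3D", "u^2D", "u^PD", "a^HD", "g^HD"))
    for (sid in c("u^3D", "u^2D", "u^PD", "a^HD", "g^HD")) {
      stream <- session$streams[[sid]]
      chans <- colnames(stream$values)
      for (j in seq_len(ncol(stream$values))) {
        nm <- if (ncol(stream$values) == 1L) sid else axis_series_name(sid, chans[j])
        out <- c(out, series_battery(nm, stream$values[, j], stream$rate_hz))
      }
    }
    out["m(u^BK)"] <- session$blink_count %||% NA_real_
    out["m(u^SC)"] <- session$saccade_count %||% NA_real_
  } else {
    ids <- paste0("r^", motion_parts)
    require_streams(session, ids)
    for (sid in ids) {
      stream <- session$streams[[sid]]
      for (j in 1:3) {
        nm <- axis_series_name(sid, c("x", "y", "z")[j])
        out <- c(out, series_battery(nm, stream$values[, j], stream$rate_hz))
      }
      bs <- basic_stats(rowMeans(stream$values))
      for (s in names(bs)) out[sprintf("%s(%s)", s, sid)] <- bs[[s]]
    }
  }
  out <- c(out, task_complexity(session$order_sheet, session$working_time_s))
  stopifnot(!anyDuplicated(names(out)))
  attr(out, "device_group") <- device_group
  out
}

#' Extract a feature matrix from a dataset
#'
#' One row per session; columns are the canonical feature names of the
#' requested device group. `meta` carries the session identifiers and
#' questionnaire responses used as regression targets.
#'
#' @param dataset a [generate_dataset()] result with streams
#' @param device_group device group to extract
#' @return an object of class `feature_matrix`: list with `X` (numeric
#'   matrix), `meta` (data.frame with `subject`, `session`, `pleasant`,
#'   `arousal`, `engagement`, `difficulty`), `device_group`
#' @export
build_feature_matrix <- function(dataset, device_group = c("pulse", "eye", "motion")) {
  device_group <- match.arg(device_group)
  stopifnot(inherits(dataset, "picking_dataset"))
  rows <- lapply(dataset$sessions, build_feature_vector, device_group = device_group)
  feature_matrix_from_rows(rows, dataset$sessions, device_group)
}

feature_matrix_from_rows <- function(rows, sessions, device_group) {
  X <- do.call(rbind, rows)
  meta <- data.frame(
    subject = vapply(sessions, `[[`, numeric(1), "subject"),
    session = vapply(sessions, `[[`, numeric(1), "session"),
    pleasant = vapply(sessions, function(s) s$questionnaire$pleasant, numeric(1)),
    arousal = vapply(sessions, function(s) s$questionnaire$arousal, numeric(1)),
    engagement = vapply(sessions, function(s) s$questionnaire$engagement, numeric(1)),
    difficulty = vapply(sessions, function(s) s$questionnaire$difficulty, numeric(1)),
    working_time_s = vapply(sessions, `[[`, numeric(1), "working_time_s")
  )
  structure(list(X = X, meta = meta, device_group = device_group),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s group: %d sessions x %d features\n",
              x$device_group, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Simulate a study and extract features session by session
#'
#' Fused generate-and-extract pipeline: each session's streams are
#' synthesized, reduced to the device group's feature vector, and discarded,
#' so full-size studies (17 x 32 sessions) fit comfortably in memory. The
#' result is identical to `build_feature_matrix(generate_dataset(cfg, seed),
#' group)` because stream seeds are derived per (session, device).
#'
#' @param cfg an [effect_config()]
#' @param seed master seed
#' @param device_group device group to extract
#' @param progress print a dot every 25 sessions
#' @return a `feature_matrix` (see [build_feature_matrix()])
#' @export
simulate_feature_matrix <- function(cfg = effect_config(), seed = 1L,
                                    device_group = c("pulse", "eye", "motion"),
                                    progress = FALSE) {
  device_group <- match.arg(device_group)
  states <- sample_latent_states(cfg$n_subjects, cfg$n_sessions, cfg, seed)
  subj_amp <- with_seed(derive_seed(seed, 301L),
                        exp(rnorm(cfg$n_subjects, 0, cfg$subject_amp_sd)))
  devices <- switch(device_group,
                    pulse = c("pulse", "motion"),  # chest IMU rides with motion
                    motion = "motion",
                    eye = "eye")
  rows <- vector("list", nrow(states))
  sessions <- vector("list", nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    sess <- synth_session(st, cfg, seed, subj_amp[st$subject], devices)
    rows[[i]] <- build_feature_vector(sess, device_group)
    sess$streams <- NULL
    sessions[[i]] <- sess
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  fm <- feature_matrix_from_rows(rows, sessions, device_group)
  fm$states <- states
  fm
}
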