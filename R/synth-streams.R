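## Synthetic sensor-stream models.
##
## Pulse wave: Gaussian-shaped pulses placed at integrated-RR event times so
## the beat detector has an exact ground truth. Movement: cadence sinusoid +
## transient picking bursts + coloured noise, with the planted affect effects
## expressed as amplitude/bandwidth modulations of specific components. Eye:
## AR(1) pupil around a state-dependent baseline, Poisson blink/saccade
## events, wandering gaze. Every device part draws from its own derived
## seed, so generating a subset of parts reproduces exactly the same values
## as a full run.

`%||%` <- function(a, b) if (is.null(a)) b else a

ar1_noise <- function(n, phi, sd_innov) {
  as.numeric(stats::filter(rnorm(n, 0, sd_innov), phi, method = "recursive"))
}

lowpass_noise <- function(n, rate_hz, cutoff_hz, sd_out) {
  w <- min(cutoff_hz / (rate_hz / 2), 0.99)
  bf <- signal::butter(2, w, type = "low")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_out
}

bandpass_noise <- function(n, rate_hz, band_hz, sd_out) {
  w <- pmin(band_hz / (rate_hz / 2), c(0.99, 0.995))
  bf <- signal::butter(2, w, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_out
}

# sum of one-sided Gaussian bumps at roughly `rate_hz` events per second
burst_train <- function(times, event_rate_hz, amp, width_s, amp_jitter = 0.3) {
  n_ev <- rpois(1L, event_rate_hz * diff(range(times)))
  out <- numeric(length(times))
  if (n_ev == 0L) return(out)
  centers <- sort(runif(n_ev, min(times), max(times)))
  amps <- amp * exp(rnorm(n_ev, 0, amp_jitter))
  rate <- 1 / median(diff(times))
  half <- ceiling(3 * width_s * rate)
  for (k in seq_len(n_ev)) {
    i0 <- findInterval(centers[k], times)
    idx <- max(1L, i0 - half):min(length(times), i0 + half)
    out[idx] <- out[idx] + amps[k] * exp(-0.5 * ((times[idx] - centers[k]) / width_s)^2)
  }
  out
}

check_duration <- function(duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 30) {
    stop("`duration_s` must exceed 30 s (one full analysis window)", call. = FALSE)
  }
}

#' Synthesize the ground-truth beat sequence of a session
#'
#' Integrates the beat-to-beat interval model
#' `RR(t) = baseline + A_LF sin(2 pi 0.1 t) + A_HF sin(2 pi 0.25 t) + noise`
#' into beat event times. The LF amplitude rises with arousal and falls with
#' concentration; the HF amplitude falls with arousal (vagal withdrawal).
#' This is the ground truth that [synthesize_pulse_wave()] renders as a
#' waveform.
#'
#' @param state one row of [sample_latent_states()] (or a list with
#'   `arousal` and `engagement`)
#' @param duration_s recording length in seconds (> 30)
#' @param cfg an [effect_config()]
#' @param seed integer seed
#' @param lf_amp,hf_amp,rr_baseline,rr_noise optional overrides (ms) of the
#'   state-derived oscillation amplitudes, baseline and beat noise
#' @return a [derived_series()] of kind `"RR"` (ms) with attribute
#'   `beat_times`
#' @export
synthesize_rr <- function(state, duration_s, cfg = effect_config(), seed = 1L,
                          lf_amp = NULL, hf_amp = NULL, rr_baseline = NULL,
                          rr_noise = NULL) {
  check_duration(duration_s)
  with_seed(derive_seed(seed, 401L), {
    arousal <- state$arousal
    eng_c <- state$engagement - 3
    baseline <- rr_baseline %||%
      (cfg$rr_baseline_ms + cfg$rr_arousal_slope_ms * arousal)
    a_lf <- lf_amp %||%
      (cfg$lf_power_gain * exp(cfg$lf_arousal_gain * arousal -
                                 cfg$lf_engagement_suppression * eng_c))
    a_hf <- hf_amp %||% (cfg$hf_power_gain * exp(-cfg$hf_arousal_suppression * arousal))
    noise <- rr_noise %||% cfg$rr_noise_ms
    phi_hf <- runif(1, 0, 2 * pi)
    beats <- numeric(ceiling(duration_s / (baseline / 1000) * 1.6) + 8L)
    rr_ms <- numeric(length(beats))
    t <- 0.15
    i <- 0L
    while (t < duration_s) {
      i <- i + 1L
      rr <- baseline + a_lf * sin(2 * pi * 0.1 * t) +
        a_hf * sin(2 * pi * 0.25 * t + phi_hf) + rnorm(1, 0, noise)
      rr <- max(rr, 250)
      beats[i] <- t
      rr_ms[i] <- rr
      t <- t + rr / 1000
    }
    beats <- beats[seq_len(i)]
    rr_ms <- rr_ms[seq_len(i)]
    out <- derived_series("RR", "model", NA_real_, beats, rr_ms)
    attr(out, "beat_times") <- beats
    out
  })
}

#' Synthesize a photoplethysmographic pulse wave
#'
#' Renders the [synthesize_rr()] beat sequence as Gaussian-shaped pulses
#' sampled at 1000 Hz (plus a small sensor-noise floor), so that beat
#' detection has an exact ground truth (attached as attributes `beat_times`
#' and `rr_ms`).
#'
#' @inheritParams synthesize_rr
#' @return a 1000 Hz [sensor_stream()] with id `"p^pulse"`
#' @export
synthesize_pulse_wave <- function(state, duration_s, cfg = effect_config(),
                                  seed = 1L, lf_amp = NULL, hf_amp = NULL,
                                  rr_baseline = NULL, rr_noise = NULL) {
  rrs <- synthesize_rr(state, duration_s, cfg, seed, lf_amp, hf_amp,
                       rr_baseline, rr_noise)
  beats <- attr(rrs, "beat_times")
  with_seed(derive_seed(seed, 402L), {
    rate <- 1000
    times <- stream_times(duration_s, rate)
    x <- numeric(length(times))
    half <- ceiling(4 * cfg$pulse_width_s * rate)
    for (b in beats) {
      i0 <- findInterval(b, times)
      idx <- max(1L, i0 - half):min(length(times), i0 + half)
      x[idx] <- x[idx] + exp(-0.5 * ((times[idx] - b) / cfg$pulse_width_s)^2)
    }
    x <- x + rnorm(length(x), 0, 0.02)
    out <- sensor_stream("p^pulse", rate, times, x, channels = "v")
    attr(out, "beat_times") <- beats
    attr(out, "rr_ms") <- rrs$values
    out
  })
}

motion_parts <- c("LH", "RH", "LA", "RA", "SL", "SR", "BT", "S1", "S2", "S3", "HD")

# resting posture (deg) and cadence swing amplitude (deg) per joint
motion_posture <- list(
  LH = c(5, -10, 0), RH = c(5, 10, 0), LA = c(-30, 15, -10), RA = c(-30, -15, 10),
  SL = c(10, 0, 5), SR = c(10, 0, -5), BT = c(0, 0, 0), S1 = c(3, 0, 0),
  S2 = c(8, 0, 0), S3 = c(12, 0, 0), HD = c(0, 0, 0)
)
motion_swing <- list(
  LH = c(4, 8, 2), RH = c(4, 8, 2), LA = c(3, 6, 2), RA = c(3, 6, 2),
  SL = c(2, 2, 1), SR = c(2, 2, 1), BT = c(2.5, 2, 1.5), S1 = c(1.5, 1, 1),
  S2 = c(1.2, 1, 0.8), S3 = c(1, 1, 0.8), HD = c(1, 1.5, 1)
)

#' Synthesize picking movement streams
#'
#' Produces the chest IMU of the pulse-wave meter (`a^S3`, `g^S3`, 1000 Hz,
#' three axes each) and the eleven joint rotation-angle streams of the motion
#' capture suit (`r^LH` ... `r^HD`, 50 Hz, axes x/y/z). Every joint carries a
#' walking-cadence sinusoid, transient picking bursts and a coloured noise
#' floor. The planted affect effects are: high-frequency (7--18 Hz) buttocks
#' z-rotation power shrinks as pleasantness rises; a 10 Hz picking-rhythm
#' component of the same channel strengthens with engagement; left-arm jitter
#' bandwidth (hence its extrema count) shrinks as arousal rises while the arm
#' is held higher; shoulder-y lift excursions shrink and thoracic-x bend
#' bursts deepen with engagement; and the erratic chest-acceleration
#' component waxes and wanes more slowly and deeply for unpleasant states.
#'
#' Each part draws from its own derived seed: `parts` may restrict
#' generation to a subset (e.g. only `"BT"`) and still reproduce exactly the
#' values a full call would give.
#'
#' @inheritParams synthesize_rr
#' @param subject_factor per-subject movement amplitude multiplier
#' @param parts which parts to generate: any of `"chest"` (the 1000 Hz IMU)
#'   and the joint codes `"LH"`, ..., `"HD"`
#' @return named list of [sensor_stream()]s
#' @export
synthesize_motion <- function(state, duration_s, cfg = effect_config(),
                              seed = 1L, subject_factor = 1,
                              parts = c("chest", motion_parts)) {
  check_duration(duration_s)
  pl <- state$pleasant
  ar <- state$arousal
  eng_c <- state$engagement - 3
  streams <- list()

  if ("chest" %in% parts) {
    with_seed(derive_seed(seed, 501L, 1L), {
      rate_c <- 1000
      tc <- stream_times(duration_s, rate_c)
      nc <- length(tc)
      cad <- 2 * pi * cfg$cadence_hz * tc
      irr_depth <- clamp(0.5 * exp(-cfg$chest_irregularity_upl * pl), 0, 0.95)
      irr_env <- 1 + irr_depth * sin(2 * pi * 0.1 * tc + runif(1, 0, 2 * pi))
      acc <- sapply(1:3, function(ax) {
        base <- cfg$chest_accel_g * c(0.3, 0.25, 1)[ax] * sin(cad + c(0, pi / 2, 0)[ax])
        err <- ar1_noise(nc, 0.995, 0.02) * irr_env
        base + err + burst_train(tc, 0.25, 0.5 * subject_factor, 0.25) +
          rnorm(nc, 0, 0.05)
      })
      streams[["a^S3"]] <- sensor_stream("a^S3", rate_c, tc, acc, c("x", "y", "z"))
      gyr <- sapply(1:3, function(ax) {
        cfg$chest_accel_g * 20 * c(0.4, 1, 0.4)[ax] * sin(cad + c(pi / 3, 0, pi / 2)[ax]) +
          ar1_noise(nc, 0.99, 0.6) * irr_env + rnorm(nc, 0, 1)
      })
      streams[["g^S3"]] <- sensor_stream("g^S3", rate_c, tc, gyr, c("x", "y", "z"))
    })
  }

  rate_m <- 50
  tm <- stream_times(duration_s, rate_m)
  nm <- length(tm)
  cadm <- 2 * pi * cfg$cadence_hz * tm
  for (part in intersect(motion_parts, parts)) {
    part_idx <- match(part, motion_parts)
    streams[[paste0("r^", part)]] <- with_seed(derive_seed(seed, 501L, 10L + part_idx), {
      pos <- motion_posture[[part]]
      swing <- motion_swing[[part]] * subject_factor
      phase <- runif(3, 0, 2 * pi)
      vals <- sapply(1:3, function(ax) {
        pos[ax] + swing[ax] * sin(cadm + phase[ax]) +
          ar1_noise(nm, 0.97, cfg$movement_noise_sd * 0.25) +
          burst_train(tm, 0.25, 1.2 * subject_factor, 0.35)
      })
      if (part == "BT") {
        hf_sd <- cfg$bt_hf_sd * subject_factor *
          exp(-cfg$buttock_rotation_pl_suppression * pl)
        rhythm <- cfg$bt_10hz_amp * exp(cfg$bt_10hz_engagement_gain * eng_c)
        vals[, 3] <- vals[, 3] + bandpass_noise(nm, rate_m, c(7, 18), hf_sd) +
          rhythm * sin(2 * pi * 10 * tm + runif(1, 0, 2 * pi))
      }
      if (part == "LA") {
        cutoff <- cfg$la_jitter_cutoff_hz *
          exp(-cfg$la_arousal_bandwidth_suppression * ar)
        for (ax in 1:3) {
          vals[, ax] <- vals[, ax] +
            lowpass_noise(nm, rate_m, cutoff, cfg$la_jitter_sd * subject_factor)
        }
        vals <- vals + (cfg$la_mean_deg - motion_posture[["LA"]][1]) +
          cfg$la_arousal_mean_slope * ar
      }
      if (part == "SL") {
        amp <- cfg$sl_burst_amp * exp(-cfg$sl_engagement_suppression * eng_c)
        vals[, 2] <- vals[, 2] + burst_train(tm, 0.3, amp * subject_factor, 0.5)
      }
      if (part == "S2") {
        amp <- cfg$s2_burst_amp * max(0.1, 1 + cfg$s2_engagement_gain * eng_c / 2)
        vals[, 1] <- vals[, 1] + burst_train(tm, 0.3, amp * subject_factor, 0.5)
      }
      sensor_stream(paste0("r^", part), rate_m, tm, vals, c("x", "y", "z"))
    })
  }
  streams
}

#' Synthesize eye-tracker streams
#'
#' Emits eye movement in XYZ coordinates (`u^3D`), the 2-D point of view
#' (`u^2D`) and pupil diameter (`u^PD`) at 40 Hz, the head-mounted
#' accelerometer/gyroscope (`a^HD`, `g^HD`) at 100 Hz, and Poisson blink and
#' saccade events. The pupil baseline rises with pleasantness, blink counts
#' rise toward sleepiness, and head z-acceleration bursts strengthen with
#' arousal.
#'
#' @inheritParams synthesize_rr
#' @param blink_rate_per_min optional override of the neutral blink rate
#' @param events_only skip waveform rendering and return only the blink and
#'   saccade events (identical to a full call's events)
#' @return list with `streams` (named [sensor_stream()]s; empty when
#'   `events_only`), `blink_count`, `saccade_count`, `blink_times`,
#'   `saccade_times`
#' @export
synthesize_eye <- function(state, duration_s, cfg = effect_config(), seed = 1L,
                           blink_rate_per_min = NULL, events_only = FALSE) {
  check_duration(duration_s)
  pl <- state$pleasant
  ar <- state$arousal
  ## events: own seed so counts reproduce without rendering streams
  ev <- with_seed(derive_seed(seed, 601L, 2L), {
    base_rate <- blink_rate_per_min %||% cfg$blink_rate_per_min
    lambda <- base_rate / 60 * duration_s * exp(-cfg$blink_rate_sleepy_gain * ar)
    blink_count <- rpois(1L, lambda)
    n_sac <- rpois(1L, cfg$saccade_rate_hz * duration_s)
    list(blink_times = sort(runif(blink_count, 0, duration_s)),
         sac_times = sort(runif(n_sac, 0, duration_s)),
         blink_count = blink_count, n_sac = n_sac)
  })
  streams <- list()
  if (!events_only) {
    streams <- with_seed(derive_seed(seed, 601L, 1L), {
      out <- list()
      rate_e <- 40
      te <- stream_times(duration_s, rate_e)
      ne <- length(te)
      wander <- function(center, scale) {
        drift <- ar1_noise(ne, 0.995, scale * 0.02)
        jumps <- numeric(ne)
        if (ev$n_sac) {
          # saccades: mean-reverting jump process so gaze stays on-screen
          idx <- pmin(findInterval(ev$sac_times, te) + 1L, ne)
          steps <- numeric(ne)
          steps[idx] <- rnorm(length(idx), 0, scale * 0.4)
          jumps <- as.numeric(stats::filter(steps, 0.98, method = "recursive"))
        }
        center + drift + jumps + rnorm(ne, 0, scale * 0.01)
      }
      u3 <- cbind(wander(400, 120), wander(420, 120), wander(600, 150))
      out[["u^3D"]] <- sensor_stream("u^3D", rate_e, te, u3, c("x", "y", "z"))
      u2 <- cbind(wander(960, cfg$gaze_wander_px), wander(540, cfg$gaze_wander_px * 0.8))
      out[["u^2D"]] <- sensor_stream("u^2D", rate_e, te, u2, c("x", "y"))
      pd_base <- cfg$pupil_baseline_mm + cfg$pupil_baseline_gain * pl
      pd <- pd_base + cfg$pupil_drift_mm * sin(2 * pi * 0.05 * te + runif(1, 0, 2 * pi)) +
        ar1_noise(ne, cfg$pupil_ar1_phi, cfg$pupil_noise_mm)
      out[["u^PD"]] <- sensor_stream("u^PD", rate_e, te, pd, "v")
      rate_h <- 100
      th <- stream_times(duration_s, rate_h)
      nh <- length(th)
      cadh <- 2 * pi * cfg$cadence_hz * th
      burst_amp <- cfg$head_burst_amp * exp(cfg$head_burst_arousal_gain * ar)
      ah <- cbind(
        0.5 * sin(cadh) + ar1_noise(nh, 0.98, 0.15) + rnorm(nh, 0, 0.2),
        -7 + 0.5 * sin(cadh + pi / 2) + ar1_noise(nh, 0.98, 0.15) + rnorm(nh, 0, 0.2),
        5.5 + 1.2 * sin(cadh) + burst_train(th, 0.3, burst_amp, 0.15) +
          ar1_noise(nh, 0.98, 0.2) + rnorm(nh, 0, 0.2)
      )
      out[["a^HD"]] <- sensor_stream("a^HD", rate_h, th, ah, c("x", "y", "z"))
      gh <- sapply(1:3, function(ax) {
        12 * sin(cadh + ax) + ar1_noise(nh, 0.97, 1.2) + rnorm(nh, 0, 1.5)
      })
      out[["g^HD"]] <- sensor_stream("g^HD", rate_h, th, gh, c("x", "y", "z"))
      out
    })
  }
  list(streams = streams, blink_count = ev$blink_count,
       saccade_count = ev$n_sac, blink_times = ev$blink_times,
       saccade_times = ev$sac_times)
}
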