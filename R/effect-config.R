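#' Synthetic-study effect configuration
#'
#' Bundles every tunable constant of the synthetic data generator: the study
#' design (subjects x sessions), the latent flow-to-questionnaire couplings,
#' and the per-signal effect sizes that plant the documented group-difference
#' directions into the sensor streams (pleasant suppresses high-frequency
#' buttocks rotation power, sleepiness raises blink counts, boredom raises
#' LF-power peak-valley level, and so on).
#'
#' `strength` scales every *effect* (couplings and planted signal gains) while
#' leaving baselines and noise untouched: `strength = 1` is the default
#' strong-effect study condition, `strength = 0` is an exact null in which
#' questionnaire answers are independent of flow and no stream carries any
#' affect signal.
#'
#' @param n_subjects number of workers (default 17)
#' @param n_sessions picking sessions per worker (default 32)
#' @param strength scalar multiplier on all planted effects (default 1)
#' @param ... named overrides for any configuration field
#' @return an object of class `effect_config`
#' @examples
#' cfg <- effect_config(n_subjects = 2, n_sessions = 4)
#' cfg$rr_baseline_ms
#' @export
effect_config <- function(n_subjects = 17, n_sessions = 32, strength = 1, ...) {
  stopifnot_scalar_count(n_subjects, "n_subjects", min = 2L)
  stopifnot_scalar_count(n_sessions, "n_sessions", min = 2L)
  base <- list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    strength = strength,
    ## latent model ---------------------------------------------------------
    target_flow_gain        = 0.6,   # clear target (period 2) raises flow
    difficulty_flow_penalty = 0.55,  # |subjective difficulty| lowers flow
    flow_noise              = 0.9,
    flow_pleasant_gain      = 1.0,
    flow_arousal_gain       = 0.85,
    flow_engagement_gain    = 1.0,
    label_noise_pleasant    = 0.8,
    label_noise_arousal     = 0.9,
    label_noise_engagement  = 0.55,
    difficulty_complex_gain = 0.8,
    difficulty_noise        = 0.7,
    subject_skill_sd        = 0.2,   # log-scale SD of per-subject skill
    ## pulse wave -----------------------------------------------------------
    rr_baseline_ms          = 800,
    rr_arousal_slope_ms     = -12,   # faster heart rate when aroused
    lf_power_gain           = 35,    # A_LF (ms) at neutral state
    lf_arousal_gain         = 0.18,  # log-gain of A_LF per arousal unit
    lf_engagement_suppression = 0.25,# concentration stabilizes LF swings
    hf_power_gain           = 18,    # A_HF (ms) at neutral state
    hf_arousal_suppression  = 0.12,  # vagal HF falls when aroused
    rr_noise_ms             = 4,
    pulse_width_s           = 0.045,
    ## chest IMU (worn with the pulse meter) --------------------------------
    chest_accel_g           = 1.0,   # cadence amplitude, m/s^2-scale units
    chest_irregularity_upl  = 0.25,  # unpleasant adds erratic accel power
    ## motion detector ------------------------------------------------------
    cadence_hz              = 2.0,
    movement_noise_sd       = 0.5,   # pink-noise floor on joint angles, deg
    bt_hf_sd                = 2.6,   # buttocks z high-freq SD, deg (neutral)
    buttock_rotation_pl_suppression = 0.25, # log-suppression per pleasant unit
    bt_10hz_amp             = 0.9,   # 10 Hz picking-rhythm amplitude, deg
    bt_10hz_engagement_gain = 0.30,  # concentration strengthens the rhythm
    la_mean_deg             = -30,   # left-arm resting rotation
    la_arousal_mean_slope   = 3.0,   # arm held higher when aroused
    la_jitter_sd            = 2.0,   # left-arm jitter SD, deg
    la_jitter_cutoff_hz     = 6.0,   # jitter bandwidth at neutral arousal
    la_arousal_bandwidth_suppression = 0.15, # fewer extrema when aroused
    sl_burst_amp            = 0.45,  # shoulder-y picking excursions, deg
    sl_engagement_suppression = 0.40,# concentration removes wasteful lifts
    s2_burst_amp            = 2.0,   # thoracic-x picking bursts, deg
    s2_engagement_gain      = 0.30,  # concentration deepens trunk bends
    subject_amp_sd          = 0.08,  # per-subject movement amplitude scatter
    ## eye tracker ----------------------------------------------------------
    pupil_baseline_mm       = 3.7,
    pupil_baseline_gain     = 0.07,  # mm per pleasant unit
    pupil_ar1_phi           = 0.97,
    pupil_noise_mm          = 0.03,
    pupil_drift_mm          = 0.35,
    blink_rate_per_min      = 20,
    blink_rate_sleepy_gain  = 0.20,  # log-gain of blink rate per sleepy unit
    saccade_rate_hz         = 2.0,
    head_burst_amp          = 2.2,   # head z-accel picking bursts
    head_burst_arousal_gain = 0.15,
    gaze_wander_px          = 120,
    ## behaviour ------------------------------------------------------------
    working_time_mean_s     = 45,
    working_time_sd_s       = 6,
    working_time_min_s      = 35,
    working_time_max_s      = 60,
    working_time_skill_slope= 4,     # skilled workers are faster
    error_rate_base         = 0.35,  # Poisson picking-error rate
    error_pleasant_suppression = 0.35,
    error_complex_gain      = 0.5
  )
  # fields scaled by `strength` (all planted effects, none of the baselines)
  effect_fields <- c(
    "target_flow_gain", "difficulty_flow_penalty",
    "flow_pleasant_gain", "flow_arousal_gain", "flow_engagement_gain",
    "rr_arousal_slope_ms", "lf_arousal_gain", "lf_engagement_suppression",
    "hf_arousal_suppression", "chest_irregularity_upl",
    "buttock_rotation_pl_suppression", "bt_10hz_engagement_gain",
    "la_arousal_mean_slope", "la_arousal_bandwidth_suppression",
    "sl_engagement_suppression", "s2_engagement_gain",
    "pupil_baseline_gain", "blink_rate_sleepy_gain",
    "head_burst_arousal_gain", "error_pleasant_suppression",
    "error_complex_gain", "working_time_skill_slope"
  )
  for (f in effect_fields) base[[f]] <- base[[f]] * strength
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad)) stop("unknown effect_config field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    base[names(dots)] <- dots
  }
  num <- vapply(base[setdiff(names(base), "strength")], function(v) all(is.finite(as.numeric(v))), logical(1))
  if (!all(num)) stop("all effect_config values must be finite", call. = FALSE)
  structure(base, class = "effect_config")
}

#' @export
print.effect_config <- function(x, ...) {
  cat(sprintf("<effect_config> %d subjects x %d sessions, effect strength %g\n",
              x$n_subjects, x$n_sessions, x$strength))
  invisible(x)
}
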