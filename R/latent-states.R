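#' Sample latent affect/engagement states for a simulated study
#'
#' Draws one latent state per (subject, session). The state model follows the
#' flow-experience account of order picking: each session has a latent flow
#' level in \[0, 1\] that rises when a clear performance target is given
#' (second half of the session sequence) and falls when the subjective task
#' difficulty moves away from the worker's skill balance point. The
#' questionnaire answers -- pleasant and arousal on the 7x7 circumplex grid
#' (-3..+3) and engagement on a 5-point scale -- are noisy monotone readouts
#' of flow, so that under the default configuration flow correlates positively
#' with all three, while `effect_config(strength = 0)` makes them independent.
#'
#' @param n_subjects,n_sessions study design counts (>= 1); default to the
#'   counts declared in `cfg`
#' @param cfg an [effect_config()]
#' @param seed integer seed; identical seed gives identical states
#' @return a data.frame of class `latent_states`, one row per (subject,
#'   session), with columns `subject`, `session`, `period`, `feedback_period`,
#'   `complexity`, `subject_skill`, `flow`, `subjective_difficulty`,
#'   `pleasant`, `arousal`, `engagement`
#' @examples
#' st <- sample_latent_states(2, 4, effect_config(2, 4), seed = 1)
#' nrow(st)  # 8
#' @export
sample_latent_states <- function(n_subjects = cfg$n_subjects,
                                 n_sessions = cfg$n_sessions,
                                 cfg = effect_config(),
                                 seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects)) {
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_sessions) || n_sessions < 1 || n_sessions != round(n_sessions)) {
    stop("`n_sessions` must be a positive integer", call. = FALSE)
  }
  with_seed(derive_seed(seed, 101L), {
    n_subjects <- as.integer(n_subjects)
    n_sessions <- as.integer(n_sessions)
    skill <- exp(rnorm(n_subjects, 0, cfg$subject_skill_sd))
    # roughly half the workers get positive feedback in period 1, half in 2
    feedback <- sample(rep(1:2, length.out = n_subjects))
    out <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      # alternate simple/complex order sheets in shuffled order
      complexity <- sample(rep(c("simple", "complex"), length.out = n_sessions))
      period <- ifelse(seq_len(n_sessions) > n_sessions / 2, 2L, 1L)
      sd_raw <- cfg$difficulty_complex_gain * (complexity == "complex") -
        cfg$difficulty_complex_gain * (complexity == "simple") / 2 -
        0.5 * log(skill[s]) + rnorm(n_sessions, 0, cfg$difficulty_noise)
      difficulty <- as.integer(clamp(round(sd_raw), -2L, 2L))
      flow_lin <- cfg$target_flow_gain * (period == 2L) -
        cfg$difficulty_flow_penalty * abs(difficulty) +
        rnorm(n_sessions, 0.2, cfg$flow_noise)
      flow <- stats::plogis(1.3 * flow_lin)
      pleasant <- as.integer(clamp(round(
        cfg$flow_pleasant_gain * (flow - 0.45) * 6 +
          rnorm(n_sessions, 0, cfg$label_noise_pleasant)), -3L, 3L))
      arousal <- as.integer(clamp(round(
        cfg$flow_arousal_gain * (flow - 0.5) * 5 +
          rnorm(n_sessions, 0, cfg$label_noise_arousal)), -3L, 3L))
      engagement <- as.integer(clamp(round(
        3 + cfg$flow_engagement_gain * (flow - 0.5) * 3.2 +
          rnorm(n_sessions, 0, cfg$label_noise_engagement)), 1L, 5L))
      out[[s]] <- data.frame(
        subject = s, session = seq_len(n_sessions), period = period,
        feedback_period = feedback[s], complexity = complexity,
        subject_skill = skill[s], flow = flow,
        subjective_difficulty = difficulty,
        pleasant = pleasant, arousal = arousal, engagement = engagement,
        stringsAsFactors = FALSE
      )
    }
    states <- do.call(rbind, out)
    rownames(states) <- NULL
    class(states) <- c("latent_states", "data.frame")
    states
  })
}

validate_state <- function(state) {
  stopifnot(
    state$pleasant >= -3, state$pleasant <= 3,
    state$arousal >= -3, state$arousal <= 3,
    state$engagement >= 1, state$engagement <= 5,
    state$subjective_difficulty >= -2, state$subjective_difficulty <= 2,
    state$flow >= 0, state$flow <= 1,
    state$subject_skill > 0,
    state$period %in% 1:2
  )
  invisible(TRUE)
}
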