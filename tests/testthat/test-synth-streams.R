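test_that("pulse oscillation amplitudes land in the declared HRV bands", {
  st <- fixture_state()
  cfg <- effect_config()
  # LF-only modulation: recovered LF band power dwarfs HF
  p <- synthesize_pulse_wave(st, 45, cfg, seed = 1, lf_amp = 30, hf_amp = 0)
  rr <- detect_rr(p)
  lf <- mean(hrv_band_series(rr, "LF")$values)
  hf <- mean(hrv_band_series(rr, "HF")$values)
  expect_gt(lf, 20 * hf)
  # constant-RR: detected mean RR within a sample of the configured baseline
  p2 <- synthesize_pulse_wave(st, 40, cfg, seed = 2, lf_amp = 0, hf_amp = 0,
                              rr_baseline = 800, rr_noise = 0)
  rr2 <- detect_rr(p2)
  expect_lt(max(abs(rr2$values - 800)), 1.5)
})

test_that("LF power rises with arousal as configured", {
  cfg <- effect_config()
  band_lf <- function(ar, seed) {
    rr <- synthesize_rr(fixture_state(arousal = ar), 45, cfg, seed = seed)
    mean(hrv_band_series(rr, "LF")$values)
  }
  hi <- mean(sapply(1:5, function(s) band_lf(3, s)))
  lo <- mean(sapply(1:5, function(s) band_lf(-3, s)))
  expect_gt(hi, lo)
})

test_that("stream rates and durations match their declarations", {
  st <- fixture_state()
  m <- synthesize_motion(st, 35, effect_config(), seed = 3)
  expect_named(m, c("a^S3", "g^S3", paste0("r^", flowpick:::motion_parts)),
               ignore.order = TRUE)
  for (stream in m) {
    expect_silent(validate_stream(stream))
    expect_equal(stream_rate <- stream$rate_hz,
                 if (stream$stream_id %in% c("a^S3", "g^S3")) 1000 else 50)
    expect_equal(nrow(stream$values), floor(35 * stream$rate_hz))
  }
  e <- synthesize_eye(st, 35, effect_config(), seed = 3)
  rates <- vapply(e$streams, `[[`, numeric(1), "rate_hz")
  expect_equal(unname(rates[c("u^3D", "u^2D", "u^PD")]), c(40, 40, 40))
  expect_equal(unname(rates[c("a^HD", "g^HD")]), c(100, 100))
})

test_that("buttocks high-frequency rotation power shrinks with pleasantness", {
  cfg <- effect_config()
  f15 <- function(pl, seed) {
    m <- synthesize_motion(fixture_state(pleasant = pl), 40, cfg,
                           seed = seed, parts = "BT")
    psd_feature(m[["r^BT"]]$values[, 3], 50, 15)
  }
  hi <- mean(sapply(1:5, function(s) f15(3, s)))
  lo <- mean(sapply(1:5, function(s) f15(-3, s)))
  expect_lt(hi, lo)
})

test_that("motion streams are seed-stable but differ across seeds", {
  st <- fixture_state(pleasant = 1)
  a <- synthesize_motion(st, 32, effect_config(), seed = 4, parts = "BT")
  b <- synthesize_motion(st, 32, effect_config(), seed = 4, parts = "BT")
  c <- synthesize_motion(st, 32, effect_config(), seed = 5, parts = "BT")
  expect_identical(a, b)
  expect_false(identical(a[["r^BT"]]$values, c[["r^BT"]]$values))
})

test_that("a zero-strength configuration plants no pleasant effect in movement", {
  cfg0 <- effect_config(strength = 0)
  f15 <- function(pl, seed) {
    m <- synthesize_motion(fixture_state(pleasant = pl), 40, cfg0,
                           seed = seed, parts = "BT")
    psd_feature(m[["r^BT"]]$values[, 3], 50, 15)
  }
  hi <- sapply(1:8, function(s) f15(3, s))
  lo <- sapply(1:8, function(s) f15(-3, s + 100))
  # same distribution: means within Monte-Carlo scatter of each other
  expect_lt(abs(mean(hi) - mean(lo)), 3 * sd(c(hi, lo)))
})

test_that("eye streams carry the planted pupil, blink and head effects", {
  cfg <- effect_config()
  pupil_min <- function(pl, seed) {
    min(synthesize_eye(fixture_state(pleasant = pl), 35, cfg, seed = seed)$streams[["u^PD"]]$values)
  }
  expect_gt(mean(sapply(1:5, function(s) pupil_min(3, s))),
            mean(sapply(1:5, function(s) pupil_min(-3, s))))
  blinks <- function(ar, seed) {
    synthesize_eye(fixture_state(arousal = ar), 35, cfg, seed = seed,
                   events_only = TRUE)$blink_count
  }
  expect_gt(mean(sapply(1:10, function(s) blinks(-3, s))),
            mean(sapply(1:10, function(s) blinks(3, s))))
  # zero blink rate yields exactly zero blinks
  none <- synthesize_eye(fixture_state(), 35, cfg, seed = 1,
                         blink_rate_per_min = 0, events_only = TRUE)
  expect_identical(none$blink_count, 0L)
})

test_that("too-short recordings are rejected by every synthesizer", {
  st <- fixture_state()
  expect_error(synthesize_pulse_wave(st, 20, effect_config(), 1), "30 s")
  expect_error(synthesize_motion(st, 30, effect_config(), 1), "30 s")
  expect_error(synthesize_eye(st, 10, effect_config(), 1), "30 s")
})
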