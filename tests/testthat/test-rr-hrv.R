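test_that("beat detection recovers a constant-spacing pulse train exactly", {
  p <- synthesize_pulse_wave(fixture_state(), 40, effect_config(), seed = 1,
                             lf_amp = 0, hf_amp = 0, rr_baseline = 800,
                             rr_noise = 0)
  rr <- detect_rr(p)
  expect_lt(max(abs(rr$values - 800)), 1.5)  # within one 1 kHz sample
  expect_equal(length(attr(rr, "beat_times")), length(attr(p, "beat_times")))
})

test_that("a 0.1 Hz RR modulation is recovered at the right spectral location", {
  p <- synthesize_pulse_wave(fixture_state(), 60, effect_config(), seed = 2,
                             lf_amp = 40, hf_amp = 0, rr_noise = 0)
  rr <- detect_rr(p)
  grid <- seq(min(rr$times), max(rr$times), by = 0.25)
  rru <- approx(rr$times, rr$values, xout = grid)$y
  bins <- psd_bins(rru, 4)
  peak <- bins$freq[which.max(bins$density[bins$freq > 0]) + 1L]
  expect_equal(peak, 0.1, tolerance = 0.05)
})

test_that("flat input yields an empty-result error", {
  flat <- sensor_stream("p^pulse", 1000, stream_times(35, 1000),
                        rep(0, 35000))
  expect_error(detect_rr(flat), "no beats")
  short <- synthesize_pulse_wave(fixture_state(), 31, effect_config(), 1)
  short$times <- short$times[1:5000]
  short$values <- short$values[1:5000, , drop = FALSE]
  expect_error(detect_rr(short), "30 s")
})

test_that("total power is exactly the sum of the three bands", {
  rr <- synthesize_rr(fixture_state(arousal = 1), 50, effect_config(), seed = 3)
  tp <- hrv_band_series(rr, "TP")
  vlf <- hrv_band_series(rr, "VLF")
  lf <- hrv_band_series(rr, "LF")
  hf <- hrv_band_series(rr, "HF")
  expect_equal(tp$values, vlf$values + lf$values + hf$values,
               tolerance = 1e-9)
  # pure 0.1 Hz modulation: LF dominates every window
  rr1 <- synthesize_rr(fixture_state(), 50, effect_config(), seed = 4,
                       lf_amp = 30, hf_amp = 0, rr_noise = 0)
  expect_true(all(hrv_band_series(rr1, "LF")$values >
                    hrv_band_series(rr1, "HF")$values))
  # constant RR: negligible band power
  rr0 <- synthesize_rr(fixture_state(), 50, effect_config(), seed = 5,
                       lf_amp = 0, hf_amp = 0, rr_noise = 0)
  expect_lt(max(hrv_band_series(rr0, "TP")$values), 1e-6)
})

test_that("windowed series obey the 30 s / 1 s sliding-length contract", {
  for (dur in c(35, 42, 58)) {
    rr <- synthesize_rr(fixture_state(), dur, effect_config(), seed = 6)
    span <- diff(range(rr$times))
    lf <- hrv_band_series(rr, "LF")
    expect_equal(length(lf$values), floor(span + 1e-9) - 29)
  }
  rr_short <- synthesize_rr(fixture_state(), 31, effect_config(), seed = 7)
  rr_short$times <- rr_short$times[1:20]
  rr_short$values <- rr_short$values[1:20]
  expect_error(hrv_band_series(rr_short, "LF"), "30 s window")
})

test_that("1 Hz RR and HR series are reciprocal", {
  rr <- synthesize_rr(fixture_state(), 40, effect_config(), seed = 8)
  rs <- rr_rate_series(rr)
  expect_equal(rs$HR$values, 60000 / rs$RR$values)
  expect_equal(rs$RR$rate_hz, 1)
})
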