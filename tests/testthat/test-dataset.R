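test_that("dataset generation is reproducible and respects the session budget", {
  cfg <- tiny_cfg()
  ds <- generate_dataset(cfg, seed = 3, streams = FALSE)
  expect_equal(length(ds$sessions), cfg$n_subjects * cfg$n_sessions)
  wt <- vapply(ds$sessions, `[[`, numeric(1), "working_time_s")
  expect_true(all(wt > 0 & wt <= 60))
  err <- vapply(ds$sessions, `[[`, numeric(1), "human_errors")
  expect_true(all(err >= 0))
  # the questionnaire equals the discretized latent state
  expect_equal(vapply(ds$sessions, function(s) s$questionnaire$pleasant, numeric(1)),
               ds$states$pleasant)
  # 9-item flow scale per (subject, period)
  expect_equal(nrow(ds$flow_scale), cfg$n_subjects * 2)
  expect_true(all(as.matrix(ds$flow_scale[, paste0("q", 1:9)]) %in% 1:7))
})

test_that("written manifests are byte-identical across reruns of one seed", {
  cfg <- tiny_cfg()
  d1 <- file.path(tempdir(), "fp_run1")
  d2 <- file.path(tempdir(), "fp_run2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(cfg, seed = 11, streams = TRUE, out_dir = d1)
  generate_dataset(cfg, seed = 11, streams = TRUE, out_dir = d2)
  m1 <- readBin(file.path(d1, "manifest.json"), "raw",
                file.size(file.path(d1, "manifest.json")))
  m2 <- readBin(file.path(d2, "manifest.json"), "raw",
                file.size(file.path(d2, "manifest.json")))
  expect_identical(m1, m2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("manifests round-trip through validation and bad ones are itemized", {
  cfg <- tiny_cfg()
  dir <- file.path(tempdir(), "fp_manifest")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(cfg, seed = 4, streams = TRUE, out_dir = dir)
  sessions <- validate_manifest(file.path(dir, "manifest.json"))
  expect_length(sessions, length(ds$sessions))
  s1 <- sessions[[1]]
  expect_s3_class(s1$streams[["p^pulse"]], "sensor_stream")
  expect_equal(s1$streams[["p^pulse"]]$rate_hz, 1000)

  # out-of-scale engagement is reported with field and session
  mpath <- file.path(dir, "manifest.json")
  m <- jsonlite::read_json(mpath)
  m$sessions[[1]]$questionnaire$engagement <- 6
  jsonlite::write_json(m, mpath, auto_unbox = TRUE, digits = NA)
  expect_error(validate_manifest(mpath, load_streams = FALSE),
               "engagement=6.*out of", ignore.case = TRUE)

  # a missing stream file is named
  m$sessions[[1]]$questionnaire$engagement <- 3
  jsonlite::write_json(m, mpath, auto_unbox = TRUE, digits = NA)
  victim <- list.files(dir, pattern = "p_pulse", recursive = TRUE,
                       full.names = TRUE)[1]
  unlink(victim)
  expect_error(validate_manifest(mpath, load_streams = FALSE), "p_pulse")
  unlink(dir, recursive = TRUE)
})

test_that("human errors fall with pleasantness", {
  cfg <- effect_config(6, 16)
  ds <- generate_dataset(cfg, seed = 9, streams = FALSE)
  err <- vapply(ds$sessions, `[[`, numeric(1), "human_errors")
  pl <- ds$states$pleasant
  expect_gt(mean(err[pl < 0]), mean(err[pl > 0]))
})
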