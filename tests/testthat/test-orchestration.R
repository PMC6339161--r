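test_that("run_all produces the full design x target x group summary", {
  rc <- run_config(cfg = effect_config(2, 10), spec = tiny_spec(pretrain = FALSE),
                   seed = 5)
  suppressWarnings(bundle <- run_all(rc))
  expect_equal(nrow(bundle$summary), 18)  # 3 targets x 3 groups x 2 designs
  expect_setequal(unique(bundle$summary$design), c("loso", "personalized"))
  expect_setequal(unique(bundle$summary$device_group), c("pulse", "eye", "motion"))
  expect_true(all(is.finite(bundle$summary$mean_error)))
  expect_true(all(bundle$summary$mean_error >= 0 & bundle$summary$mean_error <= 1))
  expect_length(bundle$selections, 9)
  expect_length(bundle$importance, 9)
  imp <- bundle$importance[["pleasant.motion"]]
  expect_s3_class(imp, "importance_table")
  expect_equal(sum(imp$effect_size), 1, tolerance = 1e-9)
})

test_that("runs are reproducible and stale output directories are refused", {
  rc <- run_config(cfg = effect_config(2, 10), spec = tiny_spec(pretrain = FALSE),
                   groups = "eye", designs = "loso", targets = "pleasant",
                   seed = 6)
  dir <- file.path(tempdir(), "fp_bundle")
  unlink(dir, recursive = TRUE)
  suppressWarnings(b1 <- run_all(rc, out_dir = dir))
  suppressWarnings(b2 <- run_all(rc))
  expect_identical(b1$summary$mean_error, b2$summary$mean_error)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "run_meta.json")))
  sm <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(sm$config_hash[1], rc$config_hash)

  rc2 <- run_config(cfg = effect_config(2, 10), spec = tiny_spec(pretrain = FALSE),
                    groups = "eye", designs = "loso", targets = "pleasant",
                    seed = 7)
  expect_error(run_all(rc2, out_dir = dir), "different configuration")
  unlink(dir, recursive = TRUE)
})

test_that("null-effect runs score like the predict-the-mean baseline", {
  rc <- run_config(cfg = effect_config(4, 10, strength = 0),
                   spec = tiny_spec(pretrain = FALSE),
                   groups = "eye", designs = "loso", targets = "engagement",
                   seed = 8)
  suppressWarnings(bundle <- run_all(rc))
  meta <- bundle$features$eye$meta
  # analytic baseline: predict each training fold's mean for the held-out subject
  base <- mean(sapply(unique(meta$subject), function(s) {
    mu <- mean(meta$engagement[meta$subject != s])
    mean(abs(meta$engagement[meta$subject == s] - mu)) / 5
  }))
  got <- bundle$summary$mean_error[1]
  expect_lt(abs(got - base), 0.02 + 1e-9)
})
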