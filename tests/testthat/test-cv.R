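test_that("LOSO folds partition by subject and reproduce across runs", {
  fm <- synthetic_features(3, 12, seed = 91)
  cv <- loso_cv(fm, "pleasant", tiny_spec(seed = 1), seed = 2)
  expect_equal(cv$n_folds, 3)
  expect_equal(cv$fold_ids, 1:3)
  expect_equal(cv$mean_error, mean(cv$fold_errors))
  cv2 <- loso_cv(fm, "pleasant", tiny_spec(seed = 1), seed = 2)
  expect_identical(cv$fold_errors, cv2$fold_errors)
  # planted linear signal at low noise: errors clearly beat chance
  expect_lt(cv$mean_error, 0.12)
})

test_that("personalized CV leaves one session out within each subject", {
  fm <- synthetic_features(2, 14, seed = 92)
  cv <- personalized_cv(fm, "engagement", tiny_spec(seed = 1), seed = 2)
  expect_equal(cv$n_folds, 2)                       # two subjects
  expect_length(cv$session_errors[["1"]], 14)       # one fold per session
  expect_equal(cv$mean_error, mean(cv$fold_errors))
  fm_small <- synthetic_features(1, 3, seed = 93)
  expect_error(personalized_cv(fm_small, "pleasant", tiny_spec()), "at least 4")
})

test_that("held-out labels cannot leak into training", {
  fm <- synthetic_features(3, 12, seed = 94)
  test_rows <- which(fm$meta$subject == 3)
  train_rows <- which(fm$meta$subject != 3)
  fit1 <- flowpick:::fold_fit_predict(fm$X, fm$meta, train_rows, test_rows,
                                      "pleasant", tiny_spec(seed = 4), 0.01,
                                      "per_fold", fold_seed = 7)
  meta_shuffled <- fm$meta
  meta_shuffled$pleasant[test_rows] <- rev(meta_shuffled$pleasant[test_rows])
  fit2 <- flowpick:::fold_fit_predict(fm$X, meta_shuffled, train_rows, test_rows,
                                      "pleasant", tiny_spec(seed = 4), 0.01,
                                      "per_fold", fold_seed = 7)
  expect_identical(fit1$pred, fit2$pred)
})

test_that("per-fold selection does not exceed global selection error on null data", {
  fm <- synthetic_features(4, 10, seed = 95)
  fm$X[, 1:3] <- matrix(rnorm(40 * 3), 40, 3)   # remove all signal
  pf <- suppressWarnings(loso_cv(fm, "arousal", tiny_spec(seed = 1),
                                 selection = "per_fold", seed = 3))
  gl <- suppressWarnings(loso_cv(fm, "arousal", tiny_spec(seed = 1),
                                 selection = "global", seed = 3))
  expect_lte(pf$mean_error, gl$mean_error + 0.05)
})

test_that("personalized models beat generalized ones under subject offsets", {
  wins <- 0
  for (s in 1:5) {
    fm <- synthetic_features(3, 20, noise = 0.4, subject_offset = 2,
                             seed = 100 + s)
    gen <- suppressWarnings(loso_cv(fm, "pleasant", tiny_spec(seed = 1), seed = s))
    per <- suppressWarnings(personalized_cv(fm, "pleasant", tiny_spec(seed = 1),
                                            seed = s))
    if (per$mean_error <= gen$mean_error) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
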