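test_that("dichotomization follows the boundary rules", {
  lab <- dichotomize(data.frame(pleasant = c(0, -1, 3), arousal = c(-1, 0, 2),
                                engagement = c(3, 2, 5)))
  expect_equal(as.character(lab$pleasant_group), c("PL", "UPL", "PL"))
  expect_equal(as.character(lab$arousal_group), c("SE", "AR", "AR"))
  expect_equal(as.character(lab$engagement_group), c("CR", "BR", "CR"))
  expect_error(dichotomize(data.frame(pleasant = 4, arousal = 0, engagement = 3)),
               "out of scale")
})

test_that("screening finds a planted feature and keeps the null rate near alpha", {
  set.seed(61)
  n <- 300
  meta <- data.frame(pleasant = sample(-3:3, n, replace = TRUE),
                     arousal = 0, engagement = 3)
  X <- cbind(planted = meta$pleasant + rnorm(n, 0, 0.5),
             matrix(rnorm(n * 400), n, 400,
                    dimnames = list(NULL, paste0("noise", 1:400))))
  sel <- select_features(X, dichotomize(meta), "pleasant")
  expect_true(sel$selected[sel$feature == "planted"])
  null_rate <- mean(sel$selected[sel$feature != "planted"])
  expect_lt(null_rate, 0.03)
})

test_that("constant features are skipped with a logged message", {
  set.seed(62)
  meta <- data.frame(pleasant = rep(c(-2, 2), each = 20), arousal = 0,
                     engagement = 3)
  X <- cbind(flat = rep(1, 40), ok = rnorm(40))
  expect_message(sel <- select_features(X, dichotomize(meta), "pleasant"),
                 "skipped 1 feature")
  expect_true(is.na(sel$p_value[sel$feature == "flat"]))
  expect_false(sel$selected[sel$feature == "flat"])
  expect_equal(attr(sel, "skipped"), "flat")
})

test_that("an empty group aborts and small groups warn", {
  meta_empty <- data.frame(pleasant = rep(2, 30), arousal = 0, engagement = 3)
  X <- matrix(rnorm(30), dimnames = list(NULL, "f"))
  expect_error(select_features(X, dichotomize(meta_empty), "pleasant"),
               "empty")
  meta_small <- data.frame(pleasant = c(rep(-2, 4), rep(2, 26)), arousal = 0,
                           engagement = 3)
  X2 <- matrix(rnorm(30), dimnames = list(NULL, "f"))
  expect_warning(select_features(X2, dichotomize(meta_small), "pleasant"),
                 "low-powered")
})

test_that("the optional Benjamini-Hochberg flag only shrinks the selected set", {
  set.seed(63)
  meta <- data.frame(pleasant = sample(-3:3, 120, replace = TRUE),
                     arousal = 0, engagement = 3)
  X <- cbind(planted = meta$pleasant + rnorm(120, 0, 0.4),
             matrix(rnorm(120 * 100), 120, 100,
                    dimnames = list(NULL, paste0("n", 1:100))))
  raw <- select_features(X, dichotomize(meta), "pleasant")
  bh <- select_features(X, dichotomize(meta), "pleasant", adjust = "BH")
  expect_true(all(bh$selected <= raw$selected))
  expect_true(bh$selected[bh$feature == "planted"])
})
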