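test_that("identical samples give the null relative effect", {
  bm <- brunner_munzel(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(bm$p_hat, 0.5)
  expect_equal(bm$statistic, 0)
  expect_equal(bm$p_value, 1)
})

test_that("complete separation gives relative effect 1", {
  bm <- brunner_munzel(1:5, 10:14)
  expect_equal(bm$p_hat, 1)
  expect_equal(bm$p_value, 0)
  expect_true(is.infinite(bm$statistic))
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(51)
  for (rep in 1:20) {
    x <- rnorm(12)
    y <- rnorm(15, 0.5)
    a <- brunner_munzel(x, y)
    b <- brunner_munzel(exp(x), exp(y))
    c <- brunner_munzel(x^3, y^3)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, c$p_value)
    expect_equal(a$p_hat, b$p_hat)
  }
})

test_that("swapping the samples mirrors the relative effect and negates the statistic", {
  set.seed(52)
  for (rep in 1:20) {
    x <- rnorm(10)
    y <- rnorm(8, 0.3)
    a <- brunner_munzel(x, y)
    b <- brunner_munzel(y, x)
    expect_equal(a$p_hat, 1 - b$p_hat)
    expect_equal(a$statistic, -b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("degenerate samples raise the documented conditions", {
  expect_error(brunner_munzel(rep(1, 5), rep(1, 4)),
               class = "flowpick_degenerate_test")
  expect_error(brunner_munzel(1, 1:5), "at least 2")
})

test_that("the t-approximation tracks the exhaustive permutation law at small n", {
  set.seed(53)
  diffs <- replicate(60, {
    x <- rnorm(sample(5:8, 1))
    y <- rnorm(sample(5:8, 1), sample(c(0, 0.5, 1.5), 1))
    p_t <- tryCatch(brunner_munzel(x, y)$p_value, error = function(e) NA)
    if (is.na(p_t)) return(NA)
    abs(p_t - oracle_bm_permutation_p(x, y))
  })
  diffs <- diffs[!is.na(diffs)]
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.15)
})

test_that("type-I error at alpha 0.01 is calibrated under the null", {
  set.seed(54)
  rejections <- replicate(3000, {
    brunner_munzel(rnorm(30), rnorm(30))$p_value < 0.01
  })
  expect_gte(mean(rejections), 0.004)
  expect_lte(mean(rejections), 0.022)
})
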