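test_that("basic stats match hand enumeration", {
  b <- basic_stats(5)
  expect_equal(b$m, 5)
  expect_equal(b$sigma, 0)
  expect_equal(b$eta, 5)
  expect_equal(b$zeta, 5)
  expect_equal(basic_stats(c(0, 1, 0, 1, 0))$c, 3)
  for (n in c(5, 9, 20)) {
    alt <- rep(c(1, -1), length.out = n)
    expect_equal(basic_stats(alt)$c, n - 2)
  }
  # population SD, not sample SD
  expect_equal(basic_stats(c(0, 2))$sigma, 1)
})

test_that("peak-valley adopts extrema outside the central band and summarizes raw values", {
  pv <- peak_valley(c(0, 1, 0, 1, 0), 0.25)
  expect_equal(pv$count, 3L)          # extrema 1, 0, 1 all far from 0.5
  expect_equal(pv$mean, 2 / 3)
  expect_equal(pv$min, 0)
  expect_equal(pv$max, 1)

  # interior extrema sit near the band center: nothing is adopted
  x <- c(0, 0.5, 0.4, 0.5, 0.4, 1)
  pv2 <- peak_valley(x, 0.49)
  expect_equal(pv2$count, 0L)
  expect_true(is.na(pv2$mean))
})

test_that("adopted count is non-increasing in the threshold", {
  set.seed(17)
  for (rep in 1:30) {
    x <- rnorm(sample(5:50, 1))
    counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99),
                     function(th) peak_valley(x, th)$count, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("peak-valley equals brute-force enumeration on random series", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(3:50, 1)
    x <- if (runif(1) < 0.2) sample(1:4, n, replace = TRUE) else rnorm(n)
    th <- sample(c(0.1, 0.15, 0.25, 0.3, 0.5, 0.75, 0.9), 1)
    got <- peak_valley(x, th)
    want <- oracle_peak_valley(x, th)
    expect_equal(got$count, want$count)
    if (want$count > 0) {
      expect_equal(got$mean, want$mean)
      expect_equal(got$min, want$min)
      expect_equal(got$max, want$max)
    }
  }
})

test_that("degenerate inputs yield an empty summary or an error", {
  pv <- peak_valley(rep(2, 10), 0.25)   # constant: normalization undefined
  expect_equal(pv$count, 0L)
  expect_true(is.na(pv$mean))
  expect_error(peak_valley(c(1, 2), 0.1), "at least 3")
  expect_error(peak_valley(rnorm(10), 1), "\\[0, 1\\)")
  expect_error(peak_valley(rnorm(10), -0.1), "\\[0, 1\\)")
})
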