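test_that("simple sheets have disjoint lists, complex sheets overlap, lines obey limits", {
  for (seed in 1:200) {
    sh <- synthesize_order_sheets("simple", seed = seed)
    areas <- lapply(sh$lists, `[[`, "area")
    if (length(areas) > 1) {
      for (i in seq_along(areas)) {
        for (j in seq_len(i - 1)) {
          expect_length(intersect(areas[[i]], areas[[j]]), 0)
        }
      }
    }
    for (df in sh$lists) {
      expect_lte(nrow(df), 3)          # each list visits at most 3 areas
      expect_true(all(df$count <= 3))  # item count per line at most 3
      expect_true(all(df$area %in% LETTERS[1:6]))
    }

    ch <- synthesize_order_sheets("complex", seed = seed)
    pairs <- utils::combn(length(ch$lists), 2)
    overlap <- any(apply(pairs, 2, function(p) {
      length(intersect(ch$lists[[p[1]]]$area, ch$lists[[p[2]]]$area)) > 0
    }))
    expect_true(overlap)
    for (df in ch$lists) expect_true(all(df$count <= 3))
  }
})

test_that("task complexity encodes area dummies and overlap as hand enumeration", {
  tc <- task_complexity(manual_sheet(list(c("A", "B", "C"))), t = 40)
  expect_length(tc, 9)
  expect_equal(unname(tc[1:6]), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(tc["m(l)"]), 0.5)       # 3 of 6 dummies set
  expect_equal(unname(tc["t"]), 40)

  # three identical single-area lists: 3 ones among 18 per-list dummies
  tc3 <- task_complexity(manual_sheet(list("A", "A", "A")), t = 20)
  expect_equal(unname(tc3[1:6]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(tc3["m(l)"]), 3 / 18)

  # empty sheet: all dummies and overlaps zero
  tc0 <- task_complexity(manual_sheet(list()), t = 10)
  expect_equal(unname(tc0[1:8]), rep(0, 8))
})

test_that("task complexity rejects invalid input", {
  sh <- manual_sheet(list(c("A", "B")))
  expect_error(task_complexity(sh, t = 0), "\\(0, 60\\]")
  expect_error(task_complexity(sh, t = 61), "\\(0, 60\\]")
  expect_error(task_complexity(manual_sheet(list("Z")), t = 30), "unknown area")
})

test_that("work efficiency is 1 - t/60 on (0, 60]", {
  expect_equal(work_efficiency(60), 0)
  expect_equal(work_efficiency(30), 0.5)
  expect_equal(work_efficiency(0.001), 1 - 0.001 / 60)
  expect_error(work_efficiency(0), "\\(0, 60\\]")
  expect_error(work_efficiency(75), "\\(0, 60\\]")
})
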