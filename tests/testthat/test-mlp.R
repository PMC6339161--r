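test_that("autoencoder pretraining reduces reconstruction loss and guards constants", {
  set.seed(71)
  X <- matrix(rnorm(120 * 10), 120, 10)
  pre <- pretrain_autoencoder(X, tiny_spec())
  for (hist in pre$losses) expect_lt(tail(hist, 1), hist[1])
  expect_warning(pretrain_autoencoder(cbind(X, const = 1), tiny_spec()),
                 "constant column")
  pre2 <- pretrain_autoencoder(X, tiny_spec())
  expect_identical(pre$params, pre2$params)  # seeded determinism
  expect_error(pretrain_autoencoder(cbind(X, NA)), "missing values")
})

test_that("training is deterministic and fits a planted linear signal", {
  set.seed(72)
  n <- 500; d <- 30
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  y <- clamp(round(2 * X[, 1] + X[, 2] + rnorm(n, 0, 0.3)), -3, 3)
  tr <- 1:400; te <- 401:500
  m <- train_regressor(X[tr, ], y[tr], network_spec(seed = 5), bounds = c(-3, 3))
  p <- predict(m, X[te, ])
  expect_lt(normalized_error(y[te], p, 7), 0.15)
  expect_true(all(p >= -3 & p <= 3))
  m2 <- train_regressor(X[tr, ], y[tr], network_spec(seed = 5), bounds = c(-3, 3))
  expect_identical(predict(m2, X[te, ]), p)
  # training loss decreases during fine-tuning
  expect_lt(mean(tail(m$train_loss, 3)), mean(head(m$train_loss, 3)))
})

test_that("a constant target is reproduced exactly", {
  set.seed(73)
  X <- matrix(rnorm(60 * 5), 60, 5)
  m <- train_regressor(X, rep(2, 60), tiny_spec(pretrain = FALSE))
  expect_lt(max(abs(predict(m, X) - 2)), 0.1)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(30), 6, 5)
  expect_error(train_regressor(X, rnorm(6)), "too few rows")
  X2 <- matrix(rnorm(200), 40, 5)
  X2[3, 2] <- NA
  expect_error(train_regressor(X2, rnorm(40)), "missing values")
  expect_error(variable_importance(structure(list(), class = "lm")),
               "trained mlp_model")
})

test_that("importance is a normalized decomposition that finds the signal carrier", {
  set.seed(74)
  n <- 400; d <- 11
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  y <- X[, 1] + rnorm(n, 0, 0.1)
  hits <- 0
  for (s in 1:5) {
    # the full study architecture, shortened training
    m <- train_regressor(X, y, network_spec(epochs = 150L, seed = s))
    imp <- variable_importance(m)
    expect_equal(sum(imp$effect_size), 1, tolerance = 1e-9)
    expect_true(all(imp$effect_size >= 0))
    if (imp$feature[1] == "x1") hits <- hits + 1
  }
  expect_gte(hits, 4)
  # single input: all importance on it
  m1 <- train_regressor(matrix(rnorm(40), dimnames = list(NULL, "only")),
                        rnorm(40), tiny_spec(pretrain = FALSE))
  expect_equal(variable_importance(m1)$effect_size, 1)
})
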