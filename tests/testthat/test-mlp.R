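# Straight-line forward oracle for a fixed two-hidden-layer model.
oracle_forward <- function(weights, biases, X) {
  out <- matrix(NA_real_, nrow(X), 2L)
  for (r in seq_len(nrow(X))) {
    a <- X[r, ]
    for (l in seq_along(weights)) {
      z <- drop(a %*% weights[[l]]) + biases[[l]]
      a <- if (l < length(weights)) pmax(z, 0) else z
    }
    e <- exp(a - max(a))
    out[r, ] <- e / sum(e)
  }
  out
}

test_that("forward pass matches hand-worked example and oracle", {
  # 1 hidden unit, identity-ish weights: input 2 -> logits (2, -2)
  m <- mdapred:::new_mlp_model(
    weights = list(matrix(1, 1, 1), matrix(c(1, -1), 1, 2)),
    biases = list(0, c(0, 0)),
    config = mlp_config(hidden_sizes = 1L), trained = TRUE)
  p <- mlp_forward(m, matrix(2, 1, 1))
  expect_equal(p[1, 2], exp(-2) / (exp(2) + exp(-2)), tolerance = 1e-12)
  expect_equal(p[1, 1], exp(2) / (exp(2) + exp(-2)), tolerance = 1e-12)

  # ReLU clips negatives: input -3 gives hidden 0 -> uniform softmax
  p2 <- mlp_forward(m, matrix(-3, 1, 1))
  expect_equal(unname(p2[1, ]), c(0.5, 0.5))

  # random tiny models against the loop oracle
  set.seed(13)
  for (i in 1:20) {
    d <- sample(2:5, 1)
    W <- list(matrix(rnorm(d * 4), d, 4), matrix(rnorm(4 * 3), 4, 3),
              matrix(rnorm(3 * 2), 3, 2))
    b <- list(rnorm(4), rnorm(3), rnorm(2))
    mo <- mdapred:::new_mlp_model(W, b, mlp_config(hidden_sizes = c(4L, 3L)),
                                  trained = TRUE)
    X <- matrix(rnorm(6 * d), 6, d)
    expect_equal(mlp_forward(mo, X), oracle_forward(W, b, X),
                 tolerance = 1e-10)
    expect_equal(rowSums(mlp_forward(mo, X)), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("training solves XOR, is deterministic, rejects one class", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0L, 1L, 1L, 0L)
  cfg <- mlp_config(hidden_sizes = 8L, max_iter = 300L, learning_rate = 0.05,
                    seed = 2L)
  model <- train_mlp(X, y, cfg)
  pred <- as.integer(predict_proba(model, X) >= 0.5)
  expect_equal(pred, y)

  model2 <- train_mlp(X, y, cfg)
  expect_identical(predict_proba(model, X), predict_proba(model2, X))

  expect_error(train_mlp(X, rep(1L, 4), cfg), "single class")
  expect_error(predict_proba(mdapred:::new_mlp_model(
    model$weights, model$biases, cfg, trained = FALSE), X), "not been trained")
})

test_that("predict_proba is the softmax positive column and in range", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c(0L, 1L), 5)
  model <- train_mlp(X, y, mlp_config(hidden_sizes = 4L, max_iter = 50L,
                                      seed = 3L))
  p <- predict_proba(model, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p, mlp_forward(model, X)[, 2L])
})

test_that("label-shuffled data gives chance-level held-out AUC", {
  aucs <- vapply(1:5, function(seed) {
    withr::with_seed(400L + seed, {
      n <- 120L
      X <- matrix(rnorm(n * 6), n, 6)
      y <- as.integer(X[, 1] + X[, 2] > 0)     # learnable signal
      y_shuf <- sample(y)                       # destroyed
      tr <- 1:80; te <- 81:n
      m <- train_mlp(X[tr, ], y_shuf[tr],
                     mlp_config(hidden_sizes = 8L, max_iter = 150L,
                                seed = seed))
      roc_pr_auc(y_shuf[te], predict_proba(m, X[te, ]))$auc
    })
  }, 0)
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
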