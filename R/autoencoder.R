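#' Sparse autoencoder configuration
#'
#' @param latent_dim Hidden-layer width (latent feature dimension).
#'   Default 128, the dimension at which reconstruction loss converges to
#'   its minimum on association data of this scale.
#' @param rho Desired mean hidden activation in (0, 1); default 0.05.
#' @param beta Weight of the KL sparsity penalty; default 1.
#' @param learning_rate Adam learning rate; default 0.001.
#' @param epochs Training epochs; default 200.
#' @param batch_size Mini-batch size, or `NULL` for full-batch (default;
#'   association matrices at this scale fit in one batch).
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @return An `ae_config` list.
#' @export
ae_config <- function(latent_dim = 128L, rho = 0.05, beta = 1,
                      learning_rate = 0.001, epochs = 200L,
                      batch_size = NULL, seed = 1L) {
  stopifnot(latent_dim >= 1L, rho > 0, rho < 1, beta >= 0,
            learning_rate > 0, epochs >= 1L,
            is.null(batch_size) || batch_size >= 1L)
  structure(list(latent_dim = as.integer(latent_dim), rho = rho, beta = beta,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "ae_config")
}

new_ae_model <- function(W_enc, b_enc, W_dec, b_dec, config) {
  stopifnot(ncol(W_enc) == config$latent_dim,
            nrow(W_dec) == config$latent_dim,
            ncol(W_dec) == nrow(W_enc),
            all(is.finite(W_enc)), all(is.finite(W_dec)))
  structure(list(W_enc = W_enc, b_enc = b_enc,
                 W_dec = W_dec, b_dec = b_dec, config = config),
            class = "sparse_ae")
}

#' @export
print.sparse_ae <- function(x, ...) {
  cat(sprintf("sparse_ae: %d -> %d -> %d, rho=%g beta=%g\n",
              nrow(x$W_enc), ncol(x$W_enc), ncol(x$W_dec),
              x$config$rho, x$config$beta))
  invisible(x)
}

ae_forward <- function(model, X) {
  H <- sigmoid(sweep(X %*% model$W_enc, 2L, model$b_enc, "+"))
  Y <- sigmoid(sweep(H %*% model$W_dec, 2L, model$b_dec, "+"))
  list(H = H, Y = Y)
}

#' Autoencoder reconstruction loss
#'
#' Mean over samples of half the squared Euclidean distance between input
#' and reconstruction.
#'
#' @param model A `sparse_ae`.
#' @param X Input matrix, one sample per row; column count must equal the
#'   model input dimension.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(model, X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite input")
  stopifnot(ncol(X) == nrow(model$W_enc))
  Y <- ae_forward(model, X)$Y
  sum((Y - X)^2) / (2 * nrow(X))
}

# KL(rho || rho_hat) with natural logs; rho_hat clamped away from {0, 1}.
kl_bernoulli <- function(rho, rho_hat) {
  rho_hat <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' KL-divergence sparsity penalty
#'
#' Sum over hidden units of the Bernoulli KL divergence between the target
#' mean activation `rho` and the unit's observed mean activation over the
#' batch (clamped to \[1e-8, 1 - 1e-8\]).
#'
#' @inheritParams reconstruction_loss
#' @return Non-negative scalar; zero iff every unit's mean activation
#'   equals `rho`.
#' @export
sparsity_penalty <- function(model, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == nrow(model$W_enc))
  rho_hat <- colMeans(ae_forward(model, X)$H)
  sum(kl_bernoulli(model$config$rho, rho_hat))
}

# Loss and analytic gradients of J = recon + beta * KL on one batch.
ae_loss_grad <- function(model, X) {
  n <- nrow(X)
  rho <- model$config$rho
  beta <- model$config$beta
  fw <- ae_forward(model, X)
  H <- fw$H; Y <- fw$Y

  recon <- sum((Y - X)^2) / (2 * n)
  rho_hat_raw <- colMeans(H)
  rho_hat <- pmin(pmax(rho_hat_raw, 1e-8), 1 - 1e-8)
  sparse <- sum(kl_bernoulli(rho, rho_hat_raw))

  dY <- (Y - X) / n
  dZ2 <- dY * Y * (1 - Y)
  gW_dec <- crossprod(H, dZ2)
  gb_dec <- colSums(dZ2)

  # d KL / d rho_hat, zeroed where the clamp is active
  kl_g <- -rho / rho_hat + (1 - rho) / (1 - rho_hat)
  kl_g[rho_hat_raw < 1e-8 | rho_hat_raw > 1 - 1e-8] <- 0
  dH <- tcrossprod(dZ2, model$W_dec) +
    matrix(beta * kl_g / n, n, length(kl_g), byrow = TRUE)
  dZ1 <- dH * H * (1 - H)
  gW_enc <- crossprod(X, dZ1)
  gb_enc <- colSums(dZ1)

  list(recon = recon, sparse = sparse, total = recon + beta * sparse,
       grads = list(W_enc = gW_enc, b_enc = gb_enc,
                    W_dec = gW_dec, b_dec = gb_dec))
}

#' Train a sparse autoencoder
#'
#' Minimizes reconstruction loss plus `beta` times the KL sparsity penalty
#' with Adam. Sigmoid activations on both the encoder and decoder layer;
#' Glorot-uniform initialisation from the seeded generator. Deterministic
#' given the config seed.
#'
#' @param X Input matrix in \[0, 1\], one entity per row.
#' @param config An [ae_config()].
#' @return List with `model` (a `sparse_ae`) and `trace`, a data frame of
#'   per-epoch `reconstruction`, `sparsity` and `total` loss evaluated on
#'   the full data.
#' @export
train_autoencoder <- function(X, config = ae_config()) {
  X <- as.matrix(X)
  stopifnot(inherits(config, "ae_config"),
            all(is.finite(X)), min(X) >= 0, max(X) <= 1)
  d <- ncol(X)
  n <- nrow(X)
  k <- config$latent_dim
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)

  with_seed(config$seed, {
    params <- list(W_enc = glorot_init(d, k), b_enc = numeric(k),
                   W_dec = glorot_init(k, d), b_dec = numeric(d))
    state <- adam_init(params)
    trace <- matrix(NA_real_, config$epochs, 3L,
                    dimnames = list(NULL, c("reconstruction", "sparsity", "total")))

    for (epoch in seq_len(config$epochs)) {
      order_idx <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- order_idx[start:min(start + bs - 1L, n)]
        model <- new_ae_model(params$W_enc, params$b_enc,
                              params$W_dec, params$b_dec, config)
        lg <- ae_loss_grad(model, X[rows, , drop = FALSE])
        if (!is.finite(lg$total)) {
          stop(sprintf("autoencoder loss became non-finite at epoch %d", epoch))
        }
        upd <- adam_step(params, lg$grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      model <- new_ae_model(params$W_enc, params$b_enc,
                            params$W_dec, params$b_dec, config)
      full <- ae_loss_grad(model, X)
      trace[epoch, ] <- c(full$recon, full$sparse, full$total)
    }
  })

  list(model = model,
       trace = data.frame(epoch = seq_len(config$epochs), trace))
}

#' Encode inputs into latent features
#'
#' Hidden-layer activations of a trained sparse autoencoder; entries lie in
#' (0, 1) by the sigmoid.
#'
#' @param model A trained `sparse_ae`.
#' @param X Input matrix with the model's input dimension.
#' @return Matrix of shape `nrow(X)` x `latent_dim`; row names carried over.
#' @export
encode <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W_enc)) {
    stop(sprintf("input width %d does not match model input dimension %d",
                 ncol(X), nrow(model$W_enc)))
  }
  H <- ae_forward(model, X)$H
  rownames(H) <- rownames(X)
  H
}
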