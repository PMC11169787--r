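#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd
#' @importFrom utils head read.delim write.table packageVersion
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Canonical disease-name form: trimmed, internal whitespace collapsed,
# lower-cased. Raw labels differ only in capitalisation/spacing between
# sources, so matching happens on this form.
normalize_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (no global mutable state across runs).
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Glorot-uniform weight matrix drawn from the current RNG stream.
glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# One Adam step on a list of parameter matrices/vectors.
# `state` carries first/second moments and the step counter.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Lloyd's k-means with k-means++ initialisation, distances via BLAS
# (||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2). Draws from the current RNG
# stream; callers wrap in with_seed(). Empty clusters are reseeded with
# the point farthest from its centre (deterministic).
kmeans_lloyd <- function(X, k, iter_max = 100L, tol = 1e-4) {
  n <- nrow(X)
  stopifnot(k >= 1L, n >= k)
  xsq <- rowSums(X^2)

  # k-means++ seeding
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- pmax(xsq - 2 * drop(X %*% centers[1L, ]) + sum(centers[1L, ]^2), 0)
  if (k > 1L) {
    for (c in 2L:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[c, ] <- X[idx, ]
      d2 <- pmin(d2, pmax(
        xsq - 2 * drop(X %*% centers[c, ]) + sum(centers[c, ]^2), 0))
    }
  }

  assign_prev <- integer(n)
  totss_prev <- Inf
  for (it in seq_len(iter_max)) {
    cross <- X %*% t(centers)                       # n x k
    csq <- rowSums(centers^2)
    dist2 <- sweep(-2 * cross, 2L, csq, "+") + xsq  # n x k (+ const cols)
    assign <- max.col(-dist2, ties.method = "first")
    sizes <- tabulate(assign, nbins = k)
    if (any(sizes == 0L)) {
      nearest <- dist2[cbind(seq_len(n), assign)]
      for (c in which(sizes == 0L)) {
        far <- which.max(nearest)
        assign[far] <- c
        nearest[far] <- -Inf
      }
      sizes <- tabulate(assign, nbins = k)
    }
    centers <- rowsum(X, assign) / sizes
    totss <- sum(pmax(dist2[cbind(seq_len(n), assign)], 0))
    converged <- identical(assign, assign_prev) ||
      (is.finite(totss_prev) && abs(totss_prev - totss) <=
         tol * max(totss_prev, .Machine$double.eps))
    assign_prev <- assign
    totss_prev <- totss
    if (converged) break
  }
  list(cluster = assign, centers = centers, iterations = it)
}

# 17-significant-digit decimal text; round-trips doubles exactly.
format_sig17 <- function(x) sprintf("%.17g", x)
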