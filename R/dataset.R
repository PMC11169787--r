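#' Decompose the adjacency matrix into entity feature matrices
#'
#' The miRNA feature matrix is the adjacency matrix itself (one row per
#' miRNA over diseases); the disease feature matrix is its transpose.
#'
#' @param md Binary miRNA x disease adjacency matrix.
#' @return List with `M_initial` (= `md`) and `D_initial` (= `t(md)`).
#' @export
decompose <- function(md) {
  stopifnot(is.matrix(md), all(md %in% c(0, 1)))
  list(M_initial = md, D_initial = t(md))
}

#' Cluster-balanced negative sampling of unknown pairs
#'
#' Unknown (zero) pairs are clustered with k-means (Lloyd, k-means++
#' initialisation, at most 100 iterations) on the concatenation of the
#' pair's adjacency row and column, the only features available before any
#' training. From each cluster, a number of pairs proportional to the
#' cluster size is drawn uniformly without replacement, adjusted by one
#' draw on the largest clusters so that the total exactly matches the
#' positive count (downsampling to a balanced set).
#'
#' @param md Binary adjacency matrix.
#' @param n_clusters Number of k-means clusters; default 23.
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @param exclude Optional integer matrix of (row, col) pairs that must not
#'   be selected (e.g. held-out evaluation edges).
#' @return Integer matrix with columns `mirna`, `disease`; every returned
#'   pair has `md == 0` and the row count equals the number of positives.
#' @export
sample_negatives <- function(md, n_clusters = 23L, seed = 1L, exclude = NULL) {
  stopifnot(is.matrix(md), all(md %in% c(0, 1)))
  pos_count <- sum(md == 1)
  unknown <- which(md == 0, arr.ind = TRUE, useNames = FALSE)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- paste(unknown[, 1L], unknown[, 2L])
    unknown <- unknown[!(key %in% paste(exclude[, 1L], exclude[, 2L])), ,
                       drop = FALSE]
  }
  u_count <- nrow(unknown)
  if (u_count < pos_count) {
    stop(sprintf("only %d eligible unknown pairs for %d positives",
                 u_count, pos_count))
  }
  if (pos_count == 0L) stop("adjacency matrix has no positives to balance")

  k <- min(as.integer(n_clusters), u_count)
  feats <- cbind(md[unknown[, 1L], , drop = FALSE],
                 t(md)[unknown[, 2L], , drop = FALSE])

  with_seed(seed, {
    km <- kmeans_lloyd(feats, k)
    sizes <- tabulate(km$cluster, nbins = k)
    quota <- round(pos_count * sizes / u_count)

    # repair rounding so quotas sum exactly to the positive count,
    # adjusting one draw at a time on the largest clusters
    ord <- order(-sizes, seq_len(k))
    i <- 1L
    while (sum(quota) < pos_count) {
      c <- ord[(i - 1L) %% k + 1L]
      if (quota[c] < sizes[c]) quota[c] <- quota[c] + 1L
      i <- i + 1L
    }
    i <- 1L
    while (sum(quota) > pos_count) {
      c <- ord[(i - 1L) %% k + 1L]
      if (quota[c] > 0L) quota[c] <- quota[c] - 1L
      i <- i + 1L
    }

    chosen <- integer(0)
    for (c in seq_len(k)) {
      members <- which(km$cluster == c)
      if (quota[c] > 0L) {
        chosen <- c(chosen, members[sample.int(length(members), quota[c])])
      }
    }
  })

  neg <- unknown[chosen, , drop = FALSE]
  colnames(neg) <- c("mirna", "disease")
  neg
}

#' Assemble a labelled pair sample set
#'
#' @param positives,negatives Integer matrices of (miRNA, disease) index
#'   pairs.
#' @return A `pair_samples` list: `pairs` (combined matrix) and `labels`
#'   (1 for positives, 0 for negatives).
#' @export
pair_samples <- function(positives, negatives) {
  pairs <- rbind(positives, negatives)
  labels <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  key <- paste(pairs[, 1L], pairs[, 2L])
  if (any(key[labels == 0L] %in% key[labels == 1L])) {
    stop("negative pairs intersect positive pairs")
  }
  structure(list(pairs = pairs, labels = labels), class = "pair_samples")
}

#' Fuse latent and similarity features into per-pair rows
#'
#' The row for pair (i, j) is the concatenation
#' `[M[i, ] | Msim[i, ] | D[j, ] | Dsim[j, ]]`: the miRNA's latent features
#' and functional-similarity profile followed by the disease's latent
#' features and semantic-similarity profile.
#'
#' @param M miRNA latent feature matrix (n_mirnas x latent_dim).
#' @param msim miRNA functional similarity matrix (n_mirnas x n_mirnas).
#' @param D Disease latent feature matrix (n_diseases x latent_dim).
#' @param dsim Disease semantic similarity matrix (n_diseases x n_diseases).
#' @param pairs Integer matrix of (miRNA, disease) index pairs.
#' @return Feature matrix, one row per pair, of width
#'   `ncol(M) + ncol(msim) + ncol(D) + ncol(dsim)`.
#' @export
fuse_features <- function(M, msim, D, dsim, pairs) {
  stopifnot(nrow(M) == nrow(msim), nrow(D) == nrow(dsim))
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  if (any(i < 1L) || any(i > nrow(M)) || any(j < 1L) || any(j > nrow(D))) {
    stop("pair index out of range")
  }
  out <- cbind(M[i, , drop = FALSE], msim[i, , drop = FALSE],
               D[j, , drop = FALSE], dsim[j, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` folds, separately within each
#' label so folds are label-stratified; fold sizes differ by at most one
#' per stratum. Deterministic given the seed.
#'
#' @param labels Binary label vector.
#' @param n_folds Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}
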