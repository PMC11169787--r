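#' Confusion counts at a score threshold
#'
#' A pair is predicted positive when its score is greater than or equal to
#' the threshold (ties predicted positive).
#'
#' @param labels Binary vector of true labels.
#' @param scores Numeric scores in \[0, 1\], aligned to `labels`.
#' @param threshold Decision threshold; default 0.5.
#' @return A `confusion_counts` list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1L & labels == 1),
                 fp = sum(pred == 1L & labels == 0),
                 tn = sum(pred == 0L & labels == 0),
                 fn = sum(pred == 0L & labels == 1)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 (2TP / (2TP + FP + FN)), true positive
#' rate and false positive rate. A zero denominator yields 0 with a
#' warning; recall and TPR are the same quantity by definition.
#'
#' @param counts A `confusion_counts` object or list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return List of the six metrics, all in \[0, 1\].
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("confusion counts are all zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; reporting 0", what))
      return(0)
    }
    num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  list(accuracy = (tp + tn) / n,
       precision = safe_div(tp, tp + fp, "precision"),
       recall = recall,
       f1 = safe_div(2 * tp, 2 * tp + fp + fn, "F1"),
       tpr = recall,
       fpr = safe_div(fp, fp + tn, "FPR"))
}

#' ROC curve, PR curve and AUC
#'
#' Sweeps every distinct score as a threshold (prediction positive at
#' score >= threshold). AUC is the trapezoid area under the ROC curve and
#' equals the Mann-Whitney concordance probability with ties counted one
#' half. The PR sweep also reports the equilibrium point, the threshold
#' where precision and recall are closest.
#'
#' @param labels Binary vector; both classes must be present.
#' @param scores Numeric score vector aligned to `labels`.
#' @return List with `roc` (data frame: threshold, fpr, tpr), `pr`
#'   (data frame: threshold, recall, precision), `auc`, and `equilibrium`
#'   (threshold, recall, precision at the equilibrium point).
#' @export
roc_pr_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  cum_tp <- cumsum(lab == 1)
  cum_fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)   # last index of each distinct score

  thr <- sc[last]
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / N),
                    tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)

  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- tp / P
  pr <- data.frame(threshold = thr, recall = recall, precision = precision)
  eq_i <- which.min(abs(precision - recall))
  list(roc = roc, pr = pr, auc = auc,
       equilibrium = list(threshold = thr[eq_i], recall = recall[eq_i],
                          precision = precision[eq_i]))
}

#' Cross-validated pipeline evaluation
#'
#' Stratified k-fold evaluation of the full feature/classifier pipeline on
#' a labelled pair set. Similarity matrices are computed once from the full
#' known topology and passed in. Within each fold the latent features are
#' recomputed from an adjacency matrix whose test-fold positives are
#' zeroed, so a test edge never informs its own features, and the
#' classifier is retrained on training pairs only.
#'
#' @param catalog An `mda_catalog` of known associations.
#' @param dsim,msim Disease and miRNA similarity matrices (computed from
#'   the full catalog/DAG).
#' @param n_folds Number of folds; default 5.
#' @param seed RNG seed controlling negative sampling, fold assignment and
#'   model initialisation.
#' @param ae_cfg,mlp_cfg Model configurations (seeds inside are re-derived
#'   from `seed` per fold).
#' @param n_clusters k-means clusters for negative sampling; default 23.
#' @param threshold Decision threshold for the scalar metrics; default 0.5.
#' @return List with `folds` (per-fold metrics data frame), `mean`, `sd`,
#'   and the fold assignment.
#' @export
cross_validate <- function(catalog, dsim, msim, n_folds = 5L, seed = 1L,
                           ae_cfg = ae_config(), mlp_cfg = mlp_config(),
                           n_clusters = 23L, threshold = 0.5) {
  stopifnot(inherits(catalog, "mda_catalog"), n_folds >= 2L)
  md <- build_adjacency(catalog)
  negatives <- sample_negatives(md, n_clusters = n_clusters, seed = seed)
  samples <- pair_samples(catalog$pairs, negatives)
  folds <- stratified_folds(samples$labels, n_folds, seed = seed + 1L)
  if (any(tabulate(folds[samples$labels == 1L], n_folds) == 0L)) {
    stop("a fold has no positive samples")
  }

  metric_names <- c("accuracy", "precision", "recall", "f1", "tpr", "fpr", "auc")
  per_fold <- matrix(NA_real_, n_folds, length(metric_names),
                     dimnames = list(NULL, metric_names))
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    md_train <- md
    test_pos <- samples$pairs[intersect(test_idx, which(samples$labels == 1L)), ,
                              drop = FALSE]
    md_train[test_pos] <- 0

    feats <- latent_features(md_train, ae_cfg, seed_base = seed + 100L * f)
    train_X <- fuse_features(feats$M, msim, feats$D, dsim,
                             samples$pairs[train_idx, , drop = FALSE])
    test_X <- fuse_features(feats$M, msim, feats$D, dsim,
                            samples$pairs[test_idx, , drop = FALSE])

    mlp_cfg_f <- mlp_cfg
    mlp_cfg_f$seed <- as.integer(seed + 100L * f + 7L)
    model <- train_mlp(train_X, samples$labels[train_idx], mlp_cfg_f)
    scores <- predict_proba(model, test_X)

    m <- classification_metrics(confusion(samples$labels[test_idx], scores,
                                          threshold))
    m$auc <- roc_pr_auc(samples$labels[test_idx], scores)$auc
    per_fold[f, ] <- unlist(m)[metric_names]
    stage_log("cv", "fold %d/%d: auc=%.4f acc=%.4f", f, n_folds,
              m$auc, m$accuracy)
  }
  df <- data.frame(fold = seq_len(n_folds), per_fold)
  list(folds = df,
       mean = colMeans(per_fold),
       sd = apply(per_fold, 2L, sd),
       fold_assignment = folds)
}

# Train the two autoencoders (rows for miRNAs, transpose for diseases)
# with consecutive seeds and return both latent matrices.
latent_features <- function(md, ae_cfg = ae_config(), seed_base = NULL) {
  cfg_m <- ae_cfg
  cfg_d <- ae_cfg
  if (!is.null(seed_base)) cfg_m$seed <- as.integer(seed_base)
  cfg_d$seed <- as.integer(cfg_m$seed + 1L)
  dec <- decompose(md)
  fit_m <- train_autoencoder(dec$M_initial, cfg_m)
  fit_d <- train_autoencoder(dec$D_initial, cfg_d)
  list(M = encode(fit_m$model, dec$M_initial),
       D = encode(fit_d$model, dec$D_initial),
       trace_M = fit_m$trace, trace_D = fit_d$trace,
       model_M = fit_m$model, model_D = fit_d$model)
}
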