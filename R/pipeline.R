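#' Default pipeline run configuration
#'
#' Aggregates every stage's tunables with their provenance: autoencoder
#' learning rate 0.001, Adam, sigmoid activations and loss = reconstruction
#' + sparsity, MLP with Adam, ReLU and 300 max iterations, and latent
#' dimension 128 follow the published parameter settings of this model
#' family; the sparsity target/weight, hidden sizes, cluster count and
#' delta defaults are this package's documented choices.
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @param out_dir Artifact directory.
#' @return A `run_config` list (schema-validated by [run_pipeline()]).
#' @export
default_run_config <- function(seed = 1L, out_dir = "mdapred-run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(synthetic = TRUE,
                 assoc = NULL, dag = NULL, dsim = NULL, msim = NULL),
    synthetic = list(n_mirnas = 300L, n_diseases = 200L, n_groups = 6L,
                     p_in = 0.3, p_out = 0.01, holdout_fraction = 0.2),
    delta = 0.5,
    n_clusters = 23L,
    ae = list(latent_dim = 128L, rho = 0.05, beta = 1, learning_rate = 0.001,
              epochs = 200L),
    mlp = list(hidden_sizes = c(128L, 64L), max_iter = 300L,
               learning_rate = 0.001, alpha = 1e-4, batch_size = NULL),
    evaluation = list(mode = "holdout", n_folds = 5L, threshold = 0.5),
    rank = list(disease = NULL, k = 30L)
  )
}

#' Read a pipeline configuration from JSON
#'
#' Unknown top-level or nested keys are rejected; missing keys take the
#' defaults of [default_run_config()].
#'
#' @param path JSON file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_config(default_run_config(), drop_empty(cfg), "config")
}

# JSON has no NULL scalar: serialized configs carry empty objects/arrays
# where a field was unset; strip them so defaults apply.
drop_empty <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_empty)
  x[vapply(x, function(v) length(v) > 0L, TRUE)]
}

merge_config <- function(base, override, where) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown %s key(s): %s", where, paste(unknown, collapse = ", ")))
  }
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(where, "$", k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full prediction pipeline
#'
#' Executes every stage in order -- data loading or synthesis, similarity
#' computation, sparse-autoencoder feature learning, negative sampling and
#' feature fusion, classifier training, evaluation, and optional ranking --
#' and writes each artifact under `config$out_dir`. Reruns with the same
#' config produce byte-identical `metrics.json`.
#'
#' @param config A config list as from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, a list with the in-memory results (catalog, model,
#'   metrics, ranking, paths).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- merge_config(default_run_config(), config, "config")
  seed <- as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # stage: data ------------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$input$synthetic)) {
    spec <- planted_spec(n_mirnas = config$synthetic$n_mirnas,
                         n_diseases = config$synthetic$n_diseases,
                         n_groups = config$synthetic$n_groups,
                         p_in = config$synthetic$p_in,
                         p_out = config$synthetic$p_out,
                         holdout_fraction = config$synthetic$holdout_fraction,
                         seed = seed)
    world <- generate_planted(spec)
    catalog <- world$catalog
    dag <- world$dag
    truth <- world$truth_pairs
    stage_log("data", "synthetic world: %d miRNAs, %d diseases, %d train / %d held-out positives",
              spec$n_mirnas, spec$n_diseases, nrow(catalog$pairs), nrow(truth))
  } else {
    if (is.null(config$input$assoc)) stop("config error: input$assoc is required")
    catalog <- read_association_list(config$input$assoc)
    dag <- if (!is.null(config$input$dag)) read_dag(config$input$dag) else NULL
    if (is.null(dag) && is.null(config$input$dsim)) {
      stop("config error: need input$dag or input$dsim for disease similarity")
    }
    stage_log("data", "catalog: %d miRNAs, %d diseases, %d pairs",
              length(catalog$mirna_names), length(catalog$disease_names),
              nrow(catalog$pairs))
  }
  md <- build_adjacency(catalog)

  # stage: similarity ------------------------------------------------------
  dsim <- if (!is.null(config$input$dsim)) {
    read_similarity_matrix(config$input$dsim)
  } else {
    disease_similarity_matrix(dag, catalog$disease_names, config$delta)
  }
  msim <- if (!is.null(config$input$msim)) {
    read_similarity_matrix(config$input$msim)
  } else {
    mirna_functional_similarity(catalog, dsim)
  }
  paths$dsim <- file.path(config$out_dir, "dsim.tsv")
  paths$msim <- file.path(config$out_dir, "msim.tsv")
  write_similarity_matrix(dsim, paths$dsim)
  write_similarity_matrix(msim, paths$msim)
  stage_log("similarity", "dsim %dx%d, msim %dx%d written",
            nrow(dsim), ncol(dsim), nrow(msim), ncol(msim))

  # stage: latent features -------------------------------------------------
  ae_cfg <- ae_config(latent_dim = config$ae$latent_dim, rho = config$ae$rho,
                      beta = config$ae$beta,
                      learning_rate = config$ae$learning_rate,
                      epochs = config$ae$epochs, seed = seed + 10L)
  feats <- latent_features(md, ae_cfg)
  paths$trace_m <- file.path(config$out_dir, "ae_loss_mirna.csv")
  paths$trace_d <- file.path(config$out_dir, "ae_loss_disease.csv")
  write.table(feats$trace_M, paths$trace_m, sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(feats$trace_D, paths$trace_d, sep = ",", quote = FALSE,
              row.names = FALSE)
  stage_log("autoencoder", "latent M %dx%d, D %dx%d; final losses %.5f / %.5f",
            nrow(feats$M), ncol(feats$M), nrow(feats$D), ncol(feats$D),
            feats$trace_M$total[nrow(feats$trace_M)],
            feats$trace_D$total[nrow(feats$trace_D)])

  # stage: samples and features -------------------------------------------
  negatives <- sample_negatives(md, n_clusters = config$n_clusters,
                                seed = seed + 20L, exclude = truth)
  samples <- pair_samples(catalog$pairs, negatives)
  paths$samples <- file.path(config$out_dir, "pair_samples.tsv")
  write.table(data.frame(mirna = catalog$mirna_names[samples$pairs[, 1L]],
                         disease = catalog$disease_names[samples$pairs[, 2L]],
                         label = samples$labels),
              paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  train_X <- fuse_features(feats$M, msim, feats$D, dsim, samples$pairs)
  stage_log("dataset", "%d balanced samples, fused width %d",
            nrow(train_X), ncol(train_X))

  # stage: classifier -------------------------------------------------------
  mlp_cfg <- mlp_config(hidden_sizes = config$mlp$hidden_sizes,
                        max_iter = config$mlp$max_iter,
                        learning_rate = config$mlp$learning_rate,
                        alpha = config$mlp$alpha,
                        batch_size = config$mlp$batch_size,
                        seed = seed + 30L)
  model <- train_mlp(train_X, samples$labels, mlp_cfg)
  stage_log("mlp", "trained on %d samples", nrow(train_X))

  # stage: evaluation -------------------------------------------------------
  metrics <- NULL
  if (!is.null(truth) && nrow(truth) > 0L &&
      identical(config$evaluation$mode, "holdout")) {
    eval_set <- holdout_eval_set(md, truth, samples$pairs, seed + 40L)
    eval_X <- fuse_features(feats$M, msim, feats$D, dsim, eval_set$pairs)
    scores <- predict_proba(model, eval_X)
    m <- classification_metrics(confusion(eval_set$labels, scores,
                                          config$evaluation$threshold))
    curves <- roc_pr_auc(eval_set$labels, scores)
    m$auc <- curves$auc
    metrics <- m
    paths$roc <- file.path(config$out_dir, "roc.csv")
    paths$pr <- file.path(config$out_dir, "pr.csv")
    write.table(curves$roc, paths$roc, sep = ",", quote = FALSE, row.names = FALSE)
    write.table(curves$pr, paths$pr, sep = ",", quote = FALSE, row.names = FALSE)
    stage_log("evaluate", "held-out AUC %.4f, accuracy %.4f", m$auc, m$accuracy)
  } else if (identical(config$evaluation$mode, "cv")) {
    cv <- cross_validate(catalog, dsim, msim,
                         n_folds = config$evaluation$n_folds, seed = seed,
                         ae_cfg = ae_cfg, mlp_cfg = mlp_cfg,
                         n_clusters = config$n_clusters,
                         threshold = config$evaluation$threshold)
    metrics <- as.list(cv$mean)
    metrics$per_fold <- cv$folds
    stage_log("evaluate", "%d-fold CV mean AUC %.4f",
              config$evaluation$n_folds, cv$mean[["auc"]])
  }

  # stage: ranking -----------------------------------------------------------
  ranking <- NULL
  if (!is.null(config$rank$disease)) {
    ranking <- rank_for_disease(model, catalog, feats$M, msim, feats$D, dsim,
                                config$rank$disease, k = config$rank$k)
    paths$ranking <- file.path(config$out_dir, "ranking.tsv")
    write_ranking(ranking, paths$ranking)
    stage_log("rank", "top-%d candidates for '%s' written",
              nrow(ranking), config$rank$disease)
  }

  paths$metrics <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(list(config = config, metrics = metrics),
                       paths$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(catalog = catalog, dsim = dsim, msim = msim,
                 latent = feats, samples = samples, model = model,
                 metrics = metrics, ranking = ranking, truth = truth,
                 paths = paths, config = config))
}

# Held-out evaluation set: the withheld positives plus an equal number of
# unknown pairs drawn uniformly, excluding every positive (train and held
# out) and the training negatives.
holdout_eval_set <- function(md, truth, used_pairs, seed) {
  md_all <- md
  md_all[truth] <- 1
  unknown <- which(md_all == 0, arr.ind = TRUE, useNames = FALSE)
  key <- paste(unknown[, 1L], unknown[, 2L])
  unknown <- unknown[!(key %in% paste(used_pairs[, 1L], used_pairs[, 2L])), ,
                     drop = FALSE]
  if (nrow(unknown) < nrow(truth)) {
    stop("not enough unused unknown pairs for a balanced held-out set")
  }
  neg <- with_seed(seed, unknown[sample.int(nrow(unknown), nrow(truth)), ,
                                 drop = FALSE])
  list(pairs = rbind(truth, neg),
       labels = c(rep(1L, nrow(truth)), rep(0L, nrow(neg))))
}
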