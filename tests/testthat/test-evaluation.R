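test_that("confusion counts follow the >= threshold rule", {
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.6, 0.4, 0.3, 0.2, 0.1)
  cc <- confusion(labels, scores, 0.5)
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 3L, fn = 2L, fp = 1L, tn = 4L))

  # threshold 0: everything positive
  cc0 <- confusion(labels, scores, 0)
  expect_equal(cc0$tn + cc0$fn, 0L)
  # perfect separation
  ccp <- confusion(labels, c(rep(0.9, 5), rep(0.1, 5)), 0.5)
  expect_equal(ccp$fp + ccp$fn, 0L)
  # ties predicted positive
  cct <- confusion(c(1, 0), c(0.5, 0.5), 0.5)
  expect_equal(cct$tp, 1L)
  expect_equal(cct$fp, 1L)

  expect_error(confusion(c(1, 0), 0.5), "length")
})

test_that("metrics match hand arithmetic and edge rules", {
  m <- classification_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 6 / 9)
  expect_equal(m$fpr, 0.2)
  expect_equal(m$recall, m$tpr)

  perfect <- suppressWarnings(
    classification_metrics(list(tp = 5, fp = 0, tn = 0, fn = 0)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$fpr, 0)  # zero denominator -> 0 with warning

  w <- testthat::capture_warnings(
    classification_metrics(list(tp = 0, fp = 0, tn = 3, fn = 0)))
  expect_true(all(grepl("zero denominator", w)))
  expect_length(w, 3L)  # recall, precision, F1 all undefined
  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "all zero")

  # recall == tpr on random counts
  set.seed(17)
  for (i in 1:20) {
    cc <- as.list(setNames(sample(0:20, 4, TRUE), c("tp", "fp", "tn", "fn")))
    if (sum(unlist(cc)) == 0) next
    mm <- suppressWarnings(classification_metrics(cc))
    expect_identical(mm$recall, mm$tpr)
  }
})

test_that("trapezoid AUC equals concordance oracle; curve endpoints sane", {
  expect_equal(roc_pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_pr_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_pr_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(23)
  for (i in 1:20) {
    n <- 200L
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    r <- roc_pr_auc(labels, scores)
    expect_equal(r$auc, oracle_auc(labels, scores), tolerance = 1e-10)
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    # AUC invariant under strictly monotone transform
    expect_equal(roc_pr_auc(labels, plogis(3 * scores - 1))$auc, r$auc,
                 tolerance = 1e-12)
  }
})

test_that("cross_validate stratifies, covers all samples, is deterministic", {
  world <- generate_planted(planted_spec(n_mirnas = 40L, n_diseases = 25L,
                                         n_groups = 2L, p_in = 0.4,
                                         p_out = 0.02, seed = 12L))
  dsim <- disease_similarity_matrix(world$dag, world$catalog$disease_names)
  msim <- suppressMessages(
    mirna_functional_similarity(world$catalog, dsim))
  ae_small <- ae_config(latent_dim = 8L, epochs = 30L)
  mlp_small <- mlp_config(hidden_sizes = 16L, max_iter = 60L)
  cv <- suppressMessages(
    cross_validate(world$catalog, dsim, msim, n_folds = 3L, seed = 5L,
                   ae_cfg = ae_small, mlp_cfg = mlp_small, n_clusters = 4L))
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  folds <- cv$fold_assignment
  expect_setequal(unique(folds), 1:3)
  expect_lte(diff(range(tabulate(folds, 3L))), 2L)

  cv2 <- suppressMessages(
    cross_validate(world$catalog, dsim, msim, n_folds = 3L, seed = 5L,
                   ae_cfg = ae_small, mlp_cfg = mlp_small, n_clusters = 4L))
  expect_identical(cv$folds, cv2$folds)
})
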