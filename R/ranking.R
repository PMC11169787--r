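#' Rank candidate miRNAs for one disease
#'
#' Scores every miRNA against the disease, removes miRNAs already known to
#' be associated, sorts by descending score with lexicographic miRNA-name
#' tie-break, and truncates to the top `k`.
#'
#' @param model A trained `mlp_model`.
#' @param features Feature matrix with one row per candidate miRNA (fused
#'   rows for the (miRNA, disease) pairs of a single disease).
#' @param mirna_names Character vector naming the rows of `features`.
#' @param known_positives Character vector of miRNA names already known to
#'   be associated with the disease; these are excluded.
#' @param k Number of top candidates to keep; default 30.
#' @return A `ranked_predictions` data frame with columns `rank`, `mirna`,
#'   `score`, at most `k` rows, scores non-increasing.
#' @export
rank_mirnas <- function(model, features, mirna_names, known_positives,
                        k = 30L) {
  stopifnot(k >= 1L, nrow(features) == length(mirna_names))
  scores <- predict_proba(model, features)
  keep <- !(mirna_names %in% known_positives)
  if (!any(keep)) {
    warning("every miRNA is a known positive for this disease; empty ranking")
    out <- data.frame(rank = integer(0), mirna = character(0),
                      score = numeric(0))
    class(out) <- c("ranked_predictions", class(out))
    return(out)
  }
  cand <- mirna_names[keep]
  sc <- scores[keep]
  ord <- order(-sc, cand)
  if (k > length(cand)) {
    warning(sprintf("k=%d exceeds the %d remaining candidates; returning all",
                    k, length(cand)))
    k <- length(cand)
  }
  top <- ord[seq_len(k)]
  if (anyDuplicated(sc[ord[seq_len(min(k + 1L, length(ord)))]])) {
    stage_log("ranking", "score ties at the top-%d boundary broken by miRNA name", k)
  }
  out <- data.frame(rank = seq_len(k), mirna = cand[top], score = sc[top])
  class(out) <- c("ranked_predictions", class(out))
  out
}

#' Rank candidates for a disease from pipeline artifacts
#'
#' Convenience wrapper around [rank_mirnas()] that builds the per-pair
#' fused features for the given disease and reads the known positives from
#' the catalog.
#'
#' @param model Trained `mlp_model`.
#' @param catalog An `mda_catalog`.
#' @param M,msim,D,dsim Latent and similarity feature matrices as in
#'   [fuse_features()].
#' @param disease Disease name (whitespace/case-insensitive match against
#'   the catalog).
#' @param k Number of top candidates; default 30.
#' @export
rank_for_disease <- function(model, catalog, M, msim, D, dsim, disease,
                             k = 30L) {
  j <- match(normalize_name(disease), normalize_name(catalog$disease_names))
  if (is.na(j)) stop("unknown disease: ", disease)
  n <- length(catalog$mirna_names)
  pairs <- cbind(seq_len(n), rep(j, n))
  features <- fuse_features(M, msim, D, dsim, pairs)
  known <- catalog$mirna_names[catalog$pairs[catalog$pairs[, 2L] == j, 1L]]
  rank_mirnas(model, features, catalog$mirna_names, known, k)
}

#' Write a ranking to TSV
#'
#' @param ranking A `ranked_predictions` data frame.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
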