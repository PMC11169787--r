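#' Planted-structure synthetic dataset specification
#'
#' Describes a bipartite miRNA-disease world with planted group structure:
#' each miRNA and disease belongs to one of `n_groups` groups; matched
#' pairs associate with probability `p_in`, unmatched with `p_out`. The
#' defaults (300 x 200, 6 groups, `p_in` 0.3, `p_out` 0.01, 20% of
#' positives held out) give a positive density of roughly 3-6%, bracketing
#' the ~3% density of curated human miRNA-disease catalogs.
#'
#' @param n_mirnas,n_diseases Universe sizes.
#' @param n_groups Number of planted groups.
#' @param p_in,p_out Association probabilities for matched/unmatched
#'   pairs; `p_out < p_in` required.
#' @param holdout_fraction Fraction of positive edges withheld as
#'   evaluation truth; default 0.2.
#' @param seed RNG seed.
#' @return A `planted_spec` list.
#' @export
planted_spec <- function(n_mirnas = 300L, n_diseases = 200L, n_groups = 6L,
                         p_in = 0.3, p_out = 0.01, holdout_fraction = 0.2,
                         seed = 1L) {
  stopifnot(n_mirnas >= 1L, n_diseases >= 1L, n_groups >= 1L,
            p_out >= 0, p_out < p_in, p_in <= 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_diseases = as.integer(n_diseases),
                 n_groups = as.integer(n_groups),
                 p_in = p_in, p_out = p_out,
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

# Balanced group assignment: sizes differ by at most one, remainders to
# the earliest groups.
balanced_groups <- function(n, k) {
  rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1L) + 1e-9)))
}

#' Generate a planted-structure dataset
#'
#' Draws a binary bipartite association matrix under the planted group
#' model, withholds a fraction of the positive edges as evaluation truth
#' (they are absent from the returned catalog), and builds a disease DAG
#' as a forest: one synthetic root per group with the group's diseases
#' attached in a random tree, so semantic similarity is high within groups
#' and zero across groups. Deterministic given the spec seed.
#'
#' @param spec A [planted_spec()].
#' @return List with `catalog` (training associations), `dag`,
#'   `truth_pairs` (held-out positive index pairs), `mirna_groups`,
#'   `disease_groups`, and `all_positive_pairs`.
#' @export
generate_planted <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  mirna_names <- sprintf("mir-%04d", seq_len(spec$n_mirnas))
  disease_names <- sprintf("disease-%04d", seq_len(spec$n_diseases))

  with_seed(spec$seed, {
    mg <- sample(balanced_groups(spec$n_mirnas, spec$n_groups))
    dg <- sample(balanced_groups(spec$n_diseases, spec$n_groups))

    match_p <- ifelse(outer(mg, dg, "=="), spec$p_in, spec$p_out)
    edges <- matrix(runif(length(match_p)) < match_p,
                    spec$n_mirnas, spec$n_diseases)
    pos <- which(edges, arr.ind = TRUE, useNames = FALSE)
    if (nrow(pos) == 0L) stop("planted spec produced zero positive edges")

    n_hold <- floor(spec$holdout_fraction * nrow(pos))
    hold_idx <- if (n_hold > 0L) sample.int(nrow(pos), n_hold) else integer(0)
    truth <- pos[hold_idx, , drop = FALSE]
    train <- pos[setdiff(seq_len(nrow(pos)), hold_idx), , drop = FALSE]
    if (nrow(train) == 0L) stop("holdout removed every positive edge")

    # forest DAG: per group a synthetic root, each disease's parent drawn
    # among the root and earlier diseases of its group
    edges_dag <- NULL
    for (g in seq_len(spec$n_groups)) {
      root <- sprintf("group-%02d-root", g)
      members <- disease_names[dg == g]
      prev <- root
      for (d in members) {
        parent <- prev[sample.int(length(prev), 1L)]
        edges_dag <- rbind(edges_dag, c(parent, d))
        prev <- c(prev, d)
      }
    }
    if (is.null(edges_dag)) edges_dag <- matrix(character(0), 0L, 2L)
  })

  roots <- sprintf("group-%02d-root", seq_len(spec$n_groups))
  dag <- new_dag(unique(c(roots, disease_names)), edges_dag)
  catalog <- new_catalog(mirna_names, disease_names, train)
  colnames(truth) <- c("mirna", "disease")
  list(catalog = catalog, dag = dag, truth_pairs = truth,
       mirna_groups = mg, disease_groups = dg,
       all_positive_pairs = pos)
}

#' Generate a random DAG
#'
#' Samples a topological order and gives each non-root node between 1 and
#' `max_parents` parents among the earlier nodes, so the result is always
#' acyclic. Substrate for similarity oracle tests.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param max_parents Maximum parents per node; default 3.
#' @param seed RNG seed.
#' @return A `disease_dag` with nodes `t01`, `t02`, ...
#' @export
generate_random_dag <- function(n_nodes, max_parents = 3L, seed = 1L) {
  stopifnot(n_nodes >= 1L, max_parents >= 1L)
  names <- sprintf("t%03d", seq_len(n_nodes))
  edges <- NULL
  with_seed(seed, {
    order_idx <- sample.int(n_nodes)
    if (n_nodes >= 2L) {
      for (pos in 2L:n_nodes) {
        node <- names[order_idx[pos]]
        n_par <- sample.int(min(max_parents, pos - 1L), 1L)
        pars <- names[order_idx[sample.int(pos - 1L, n_par)]]
        edges <- rbind(edges, cbind(pars, node))
      }
    }
  })
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  new_dag(names, edges)
}
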