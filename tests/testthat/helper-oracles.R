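# Independent oracles used to freeze expected values. These deliberately
# use brute-force path enumeration / pairwise counting, not the package's
# own algorithms.

# All directed paths t ~> target in the DAG (following child edges, i.e.
# walking parents map in reverse). Returns the maximal delta^length over
# paths, or NULL if no path. Exponential; only for tiny DAGs.
oracle_contribution <- function(dag, target, t, delta) {
  if (t == target) return(1)
  # children map
  children <- lapply(setNames(dag$nodes, dag$nodes), function(x) character(0))
  for (ch in dag$nodes) {
    for (p in dag$parents[[ch]]) children[[p]] <- c(children[[p]], ch)
  }
  best <- -Inf
  walk <- function(node, depth) {
    if (node == target) {
      best <<- max(best, delta^depth)
      return()
    }
    for (ch in children[[node]]) walk(ch, depth + 1L)
  }
  walk(t, 0L)
  if (is.finite(best)) best else NULL
}

# Full profile by enumeration over the ancestor closure.
oracle_profile <- function(dag, target, delta) {
  closure <- character(0)
  frontier <- target
  while (length(frontier) > 0L) {
    closure <- c(closure, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), closure)
  }
  contrib <- vapply(closure, function(t)
    oracle_contribution(dag, target, t, delta), 0)
  list(contributions = contrib, semantic_value = sum(contrib))
}

oracle_similarity <- function(dag, a, b, delta) {
  pa <- oracle_profile(dag, a, delta)
  pb <- oracle_profile(dag, b, delta)
  shared <- intersect(names(pa$contributions), names(pb$contributions))
  if (length(shared) == 0L) return(0)
  sum(pa$contributions[shared] + pb$contributions[shared]) /
    (pa$semantic_value + pb$semantic_value)
}

# Mann-Whitney concordance AUC: P(score_pos > score_neg) + 0.5 P(equal).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Central finite-difference gradient of scalar function f at params
# (a named list of arrays); returns list of same shapes.
oracle_grad <- function(f, params, eps = 1e-6) {
  lapply(params, function(p) p)  # shape template
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]]
    for (i in seq_along(g)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[i] <- (f(pp) - f(pm)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# DAG built directly from an edge matrix (parent, child), bypassing file IO.
make_dag <- function(edges, extra_nodes = character(0)) {
  edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  mdapred:::new_dag(unique(c(edges[, 1L], edges[, 2L], extra_nodes)), edges)
}

make_catalog <- function(mirnas, diseases, pairs) {
  mdapred:::new_catalog(mirnas, diseases, matrix(pairs, ncol = 2L, byrow = TRUE))
}
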