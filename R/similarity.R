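#' Semantic profile of a disease term over an ontology DAG
#'
#' Computes the Wang-style semantic contribution of every ancestor `t` of a
#' disease `A` (including `A` itself): the contribution of `A` to itself is
#' 1, and the contribution of any other ancestor is the maximum over its
#' children inside `A`'s ancestor closure of `delta` times the child's
#' contribution, so contributions decay by `delta` per hierarchy step along
#' the best path. The semantic value `DV(A)` is the sum of all
#' contributions.
#'
#' @param dag A `disease_dag`.
#' @param term Disease term identifier; must be a node of `dag`.
#' @param delta Semantic contribution decay factor in (0, 1). Default 0.5,
#'   the standard value for MeSH disease hierarchies.
#' @return A `semantic_profile`: list with `disease`, `contributions`
#'   (named numeric over the ancestor closure), `semantic_value` and
#'   `delta`.
#' @seealso [disease_semantic_similarity()], [disease_similarity_matrix()]
#' @export
semantic_profile <- function(dag, term, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  if (!(term %in% dag$nodes)) stop("term not in DAG: ", term)

  # ancestor closure T(A)
  closure <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    closure <- c(closure, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), closure)
  }

  # children restricted to the closure: edges p -> u with both inside T(A)
  children_in <- setNames(vector("list", length(closure)), closure)
  for (u in closure) {
    for (p in intersect(dag$parents[[u]], closure)) {
      children_in[[p]] <- c(children_in[[p]], u)
    }
  }

  contrib <- setNames(rep(NA_real_, length(closure)), closure)
  contrib[term] <- 1
  compute <- function(t) {
    if (!is.na(contrib[t])) return(contrib[t])
    vals <- vapply(children_in[[t]], compute, 0)
    contrib[t] <<- delta * max(vals)
    contrib[t]
  }
  for (t in closure) compute(t)

  structure(
    list(disease = term, contributions = contrib,
         semantic_value = sum(contrib), delta = delta),
    class = "semantic_profile"
  )
}

#' Semantic similarity of two disease terms
#'
#' Shared-ancestor contribution ratio: the contributions of every term in
#' the intersection of the two ancestor closures are summed from both
#' profiles and divided by the sum of the two semantic values. The result
#' lies in \[0, 1\], is symmetric, and equals 1 for a term against itself.
#'
#' @param prof_a,prof_b `semantic_profile`s computed with the same `delta`
#'   on the same DAG.
#' @return Similarity in \[0, 1\].
#' @export
disease_semantic_similarity <- function(prof_a, prof_b) {
  stopifnot(inherits(prof_a, "semantic_profile"),
            inherits(prof_b, "semantic_profile"))
  if (prof_a$delta != prof_b$delta) {
    stop("profiles computed with different delta values")
  }
  if (prof_a$disease == prof_b$disease) return(1)
  shared <- intersect(names(prof_a$contributions), names(prof_b$contributions))
  if (length(shared) == 0L) return(0)
  s <- sum(prof_a$contributions[shared] + prof_b$contributions[shared]) /
    (prof_a$semantic_value + prof_b$semantic_value)
  min(max(s, 0), 1)
}

#' Pairwise disease semantic similarity matrix
#'
#' Applies [disease_semantic_similarity()] to every pair of the requested
#' diseases. Diseases absent from the DAG get similarity 0 to all others
#' and 1 to themselves, with a warning.
#'
#' @param dag A `disease_dag`.
#' @param diseases Ordered character vector of disease terms.
#' @param delta Decay factor in (0, 1).
#' @return Symmetric similarity matrix with unit diagonal, labelled by
#'   `diseases`.
#' @export
disease_similarity_matrix <- function(dag, diseases, delta = 0.5) {
  stopifnot(!anyDuplicated(diseases))
  n <- length(diseases)
  covered <- diseases %in% dag$nodes
  if (!all(covered)) {
    warning(sprintf("%d disease(s) missing from the DAG get self-only similarity: %s",
                    sum(!covered),
                    paste(head(diseases[!covered], 5L), collapse = ", ")))
  }
  profiles <- setNames(vector("list", n), diseases)
  for (d in diseases[covered]) profiles[[d]] <- semantic_profile(dag, d, delta)

  m <- diag(1, n)
  dimnames(m) <- list(diseases, diseases)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (!covered[i]) next
      for (j in seq(i + 1L, n)) {
        if (!covered[j]) next
        m[i, j] <- m[j, i] <-
          disease_semantic_similarity(profiles[[diseases[i]]],
                                      profiles[[diseases[j]]])
      }
    }
  }
  validate_similarity_matrix(m)
}

#' miRNA functional similarity from associated disease sets
#'
#' Best-match aggregation: for miRNAs `u`, `v` with associated disease sets
#' `DT(u)`, `DT(v)`, each disease of one set contributes its best semantic
#' similarity to any disease of the other set, and the two sums are
#' normalized by the total set size. A miRNA with an empty disease set gets
#' similarity 0 to all others and 1 to itself (logged).
#'
#' @param catalog An `mda_catalog`.
#' @param dsim Disease semantic similarity matrix covering every disease of
#'   the catalog (labels must match `catalog$disease_names`).
#' @return Symmetric miRNA similarity matrix with unit diagonal.
#' @export
mirna_functional_similarity <- function(catalog, dsim) {
  stopifnot(inherits(catalog, "mda_catalog"))
  if (!all(catalog$disease_names %in% rownames(dsim))) {
    stop("dsim does not cover all catalog diseases")
  }
  dsim <- dsim[catalog$disease_names, catalog$disease_names]
  n <- length(catalog$mirna_names)
  dt <- split(catalog$pairs[, 2L], factor(catalog$pairs[, 1L], levels = seq_len(n)))
  empty <- lengths(dt) == 0L
  if (any(empty)) {
    stage_log("similarity", "%d miRNA(s) with no associated disease get self-only similarity",
              sum(empty))
  }

  # colmax[[v]][d] = best similarity of disease d to any disease of DT(v)
  colmax <- lapply(dt, function(ds) {
    if (length(ds) == 0L) return(NULL)
    apply(dsim[, ds, drop = FALSE], 1L, max)
  })

  m <- diag(1, n)
  dimnames(m) <- list(catalog$mirna_names, catalog$mirna_names)
  if (n >= 2L) {
    for (u in seq_len(n - 1L)) {
      if (empty[u]) next
      du <- dt[[u]]
      for (v in seq(u + 1L, n)) {
        if (empty[v]) next
        s <- (sum(colmax[[v]][du]) + sum(colmax[[u]][dt[[v]]])) /
          (length(du) + length(dt[[v]]))
        m[u, v] <- m[v, u] <- min(max(s, 0), 1)
      }
    }
  }
  validate_similarity_matrix(m)
}
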