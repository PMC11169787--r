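#' Read a miRNA-disease association list
#'
#' Parses a two-column tab-separated file (miRNA name, disease name) into an
#' association catalog. Names are deduplicated preserving first-seen order;
#' duplicate pairs are collapsed with a warning. Disease names are matched
#' case-insensitively after whitespace normalization; every fold is logged.
#'
#' @param path Path to a UTF-8 TSV file with two columns. A header line is
#'   detected and skipped when its first field is one of `mirna`, `mi_rna`
#'   or `name` (case-insensitive).
#' @return An object of class `mda_catalog` with fields `mirna_names`,
#'   `disease_names` (first-seen order) and `pairs`, an integer matrix with
#'   columns `mirna` and `disease` holding 1-based indices.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("mir-1\tasthma", "mir-1\tstroke", "mir-2\tasthma"), tf)
#' cat <- read_association_list(tf)
#' cat$mirna_names
#' @export
read_association_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1L]][1L]))
  line_no <- seq_along(lines)
  if (first %in% c("mirna", "mi_rna", "name", "#mirna")) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
    if (length(fields) == 0L) stop("association file has only a header: ", path)
  }
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed association line %d (expected 2 tab-separated fields): %s",
                 line_no[bad[1L]], lines[line_no[bad[1L]]]))
  }

  mirna_raw <- trimws(vapply(fields, `[[`, "", 1L))
  disease_raw <- trimws(vapply(fields, `[[`, "", 2L))
  disease_norm <- normalize_name(disease_raw)
  folded <- disease_norm != disease_raw
  if (any(folded)) {
    for (d in unique(disease_raw[folded])) {
      stage_log("io", "disease name '%s' normalized to '%s'", d, normalize_name(d))
    }
  }

  mirna_names <- unique(mirna_raw)
  disease_names <- unique(disease_norm)
  pairs <- cbind(mirna = match(mirna_raw, mirna_names),
                 disease = match(disease_norm, disease_names))
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sprintf("%d duplicate association pair(s) collapsed", sum(dup)))
    pairs <- pairs[!dup, , drop = FALSE]
  }
  new_catalog(mirna_names, disease_names, pairs)
}

new_catalog <- function(mirna_names, disease_names, pairs) {
  stopifnot(!anyDuplicated(mirna_names), !anyDuplicated(disease_names))
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("mirna", "disease")))
  stopifnot(all(pairs[, 1L] >= 1L), all(pairs[, 1L] <= length(mirna_names)),
            all(pairs[, 2L] >= 1L), all(pairs[, 2L] <= length(disease_names)),
            !anyDuplicated(pairs))
  structure(
    list(mirna_names = mirna_names, disease_names = disease_names,
         pairs = pairs),
    class = "mda_catalog"
  )
}

#' @export
print.mda_catalog <- function(x, ...) {
  cat(sprintf("mda_catalog: %d miRNAs x %d diseases, %d known pairs\n",
              length(x$mirna_names), length(x$disease_names), nrow(x$pairs)))
  invisible(x)
}

#' Write an association catalog back to its TSV form
#'
#' @param catalog An `mda_catalog`.
#' @param path Output path.
#' @export
write_association_list <- function(catalog, path) {
  df <- data.frame(mirna = catalog$mirna_names[catalog$pairs[, 1L]],
                   disease = catalog$disease_names[catalog$pairs[, 2L]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the binary miRNA x disease adjacency matrix
#'
#' Entry (i, j) is 1 exactly when miRNA i is a known association partner of
#' disease j in the catalog, 0 elsewhere.
#'
#' @param catalog An `mda_catalog`.
#' @return Binary matrix with miRNA row names and disease column names.
#' @export
build_adjacency <- function(catalog) {
  stopifnot(inherits(catalog, "mda_catalog"))
  md <- matrix(0, length(catalog$mirna_names), length(catalog$disease_names),
               dimnames = list(catalog$mirna_names, catalog$disease_names))
  md[catalog$pairs] <- 1
  md
}

#' Extract the catalog encoded by a binary adjacency matrix
#'
#' Inverse of [build_adjacency()] up to pair order.
#'
#' @param md Binary matrix with row and column names.
#' @return An `mda_catalog`.
#' @export
extract_catalog <- function(md) {
  stopifnot(is.matrix(md), all(md %in% c(0, 1)),
            !is.null(rownames(md)), !is.null(colnames(md)))
  idx <- which(md == 1, arr.ind = TRUE, useNames = FALSE)
  new_catalog(rownames(md), colnames(md), idx)
}

#' Read a disease ontology DAG from a parent/child edge list
#'
#' The file is a two-column TSV `parent<TAB>child`; an isolated node may be
#' declared as `node<TAB>-`. Cycles are rejected with an error naming one
#' offending cycle. Disease names are whitespace/case-normalized.
#'
#' @param path Path to the edge-list TSV.
#' @return An object of class `disease_dag`: fields `nodes` (character) and
#'   `parents` (named list mapping each node to its parent nodes).
#' @export
read_dag <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed DAG line %d (expected 'parent<TAB>child'): %s",
                 bad[1L], lines[bad[1L]]))
  }
  parent <- normalize_name(vapply(fields, `[[`, "", 1L))
  child <- normalize_name(vapply(fields, `[[`, "", 2L))
  isolated <- child == "-"
  edges <- cbind(parent[!isolated], child[!isolated])
  nodes <- unique(c(parent[!isolated], child[!isolated], parent[isolated]))
  new_dag(nodes, edges)
}

# Construct and validate a disease_dag from a node set and parent->child
# edge matrix; errors on cycles, reporting one.
new_dag <- function(nodes, edges) {
  stopifnot(!anyDuplicated(nodes))
  parents <- vector("list", length(nodes))
  names(parents) <- nodes
  for (i in seq_along(parents)) parents[[i]] <- character(0)
  if (nrow(edges) > 0L) {
    stopifnot(all(edges %in% nodes))
    for (r in seq_len(nrow(edges))) {
      p <- edges[r, 1L]; ch <- edges[r, 2L]
      if (!(p %in% parents[[ch]])) parents[[ch]] <- c(parents[[ch]], p)
    }
  }
  dag <- structure(list(nodes = nodes, parents = parents),
                   class = "disease_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("cycle detected in DAG: ", paste(cyc, collapse = " -> "))
  }
  dag
}

# Returns one directed cycle (as a node path) or NULL if acyclic.
find_cycle <- function(dag) {
  color <- setNames(rep(0L, length(dag$nodes)), dag$nodes)  # 0 new 1 open 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(u) {
    if (!is.null(found)) return()
    color[u] <<- 1L
    stack <<- c(stack, u)
    for (p in dag$parents[[u]]) {      # edge p -> u; walk child -> parent
      if (color[p] == 1L) {
        i <- match(p, stack)
        found <<- c(stack[seq(i, length(stack))], p)
        return()
      }
      if (color[p] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    color[u] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (u in dag$nodes) if (color[u] == 0L) visit(u)
  found
}

#' @export
print.disease_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("disease_dag: %d nodes, %d parent->child edges\n",
              length(x$nodes), n_edges))
  invisible(x)
}

#' Write a disease DAG as a parent/child edge list
#'
#' Isolated nodes are written as `node<TAB>-` so that read/write round-trips.
#'
#' @param dag A `disease_dag`.
#' @param path Output path.
#' @export
write_dag <- function(dag, path) {
  out <- character(0)
  touched <- character(0)
  for (ch in dag$nodes) {
    for (p in dag$parents[[ch]]) {
      out <- c(out, paste(p, ch, sep = "\t"))
      touched <- c(touched, p, ch)
    }
  }
  isolated <- setdiff(dag$nodes, touched)
  if (length(isolated) > 0L) {
    out <- c(out, paste(isolated, "-", sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a similarity matrix from labelled TSV
#'
#' Expects a square numeric TSV with a header row and a leading name column.
#' Values must lie in \[0, 1\], the matrix must be symmetric within 1e-9 and
#' have unit diagonal; it is exactly symmetrized and the diagonal forced to
#' 1 on return.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with matching row/column names.
#' @export
read_similarity_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("similarity matrix is not square: %d x %d", nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("similarity matrix row and column labels differ")
  }
  validate_similarity_matrix(m, sym_tol = 1e-9, diag_tol = 1e-9)
}

# Shared invariant checks for similarity matrices; returns the cleaned
# (exactly symmetric, unit-diagonal) matrix.
validate_similarity_matrix <- function(m, sym_tol = 1e-12, diag_tol = 1e-12) {
  if (any(!is.finite(m))) stop("similarity matrix has non-finite entries")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop(sprintf("similarity entries outside [0, 1]: range %g..%g",
                 min(m), max(m)))
  }
  if (max(abs(m - t(m))) > sym_tol) {
    stop(sprintf("similarity matrix asymmetric beyond %g (max dev %g)",
                 sym_tol, max(abs(m - t(m)))))
  }
  if (max(abs(diag(m) - 1)) > diag_tol) {
    stop("similarity matrix diagonal differs from 1")
  }
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  m
}

#' Write a similarity matrix as labelled TSV
#'
#' Values are written with 17 significant digits so that write/read
#' round-trips are exact on the decimal text representation.
#'
#' @param m Similarity matrix with row/column names.
#' @param path Output path.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  body <- apply(m, 1L, function(r) paste(format_sig17(r), collapse = "\t"))
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
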