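# Sparse pair features over the global GO term universe. Each pair yields two
# instances: a target instance built from the genes' own annotations and a
# homolog instance built from homolog-transferred annotations. Component g is
# 2 when both genes carry term g, 1 when exactly one does, 0 otherwise.
# Annotations are used as given: ancestor terms in the DAG are deliberately
# NOT propagated, which keeps inter-feature correlation low.

#' Build the global GO term index
#'
#' The feature space is the union of all target and homolog terms over the
#' training-set genes, ordered lexicographically so that model coefficients
#' are reproducible across runs. Terms seen only at test time are not in the
#' index and are discarded at encoding time.
#'
#' @param training_genes Character vector of training-set gene ids.
#' @param target,homolog [annotation_set()] objects.
#' @return Object of class `term_index`: a sorted character vector of term ids.
#' @export
build_term_index <- function(training_genes, target, homolog) {
  training_genes <- unique(training_genes)
  if (length(training_genes) == 0L) stop("empty training gene set")
  terms <- sort(unique(c(
    unlist(target$annotations[intersect(training_genes, names(target$annotations))],
           use.names = FALSE),
    unlist(homolog$annotations[intersect(training_genes, names(homolog$annotations))],
           use.names = FALSE))))
  if (length(terms) == 0L) stop("no GO terms found for the training genes")
  structure(terms, class = "term_index")
}

#' Encode one gene pair as a sparse feature vector
#'
#' Component `g` of the vector is `(g annotates geneA) + (g annotates geneB)`,
#' i.e. 2 for shared terms, 1 for terms on exactly one gene, 0 elsewhere.
#' The encoding is symmetric in gene order; terms outside the index contribute
#' nothing. A pair of unannotated genes yields an all-zero vector (flagged by
#' the caller, not an error).
#'
#' @param geneA,geneB Gene ids.
#' @param ann An [annotation_set()] (target or homolog).
#' @param index A `term_index`.
#' @return A sparse numeric vector (`Matrix::sparseVector`) of length
#'   `length(index)`.
#' @export
encode_pair <- function(geneA, geneB, ann, index) {
  ta <- intersect(gene_terms(ann, geneA), index)
  tb <- intersect(gene_terms(ann, geneB), index)
  tab <- table(c(ta, tb))
  Matrix::sparseVector(as.numeric(tab), i = match(names(tab), index),
                       length = length(index))
}

#' Encode many pairs as a sparse feature matrix
#'
#' @param pairs Data frame with columns `geneA`, `geneB`.
#' @param ann An [annotation_set()].
#' @param index A `term_index`.
#' @return A `dgCMatrix` with one row per pair and `length(index)` columns.
#' @export
pair_feature_matrix <- function(pairs, ann, index) {
  n <- nrow(pairs)
  p <- length(index)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  termpos <- stats::setNames(seq_len(p), unclass(index))
  for (r in seq_len(n)) {
    ta <- gene_terms(ann, pairs$geneA[r])
    tb <- gene_terms(ann, pairs$geneB[r])
    tab <- table(c(ta, tb))
    pos <- termpos[names(tab)]
    ok <- !is.na(pos)
    if (any(ok)) {
      ii <- c(ii, rep.int(r, sum(ok)))
      jj <- c(jj, unname(pos[ok]))
      xx <- c(xx, as.numeric(tab)[ok])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p),
                       dimnames = list(NULL, unclass(index)))
}

#' Export a sparse feature matrix in coordinate text format
#'
#' Writes `row<TAB>col<TAB>value` triplets (1-based) plus a sidecar file
#' listing the term index, one term per line in column order.
#'
#' @param m A sparse matrix from [pair_feature_matrix()].
#' @param path Output path for the triplets; the index goes to
#'   `paste0(path, ".index")`.
#' @export
write_feature_matrix <- function(m, path) {
  tm <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  utils::write.table(data.frame(row = tm$i, col = tm$j, value = tm$x),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), paste0(path, ".index"))
  invisible(path)
}
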