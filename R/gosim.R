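# Wang-measure GO semantic similarity. For a term A, its induced ancestor
# graph DAG_A carries an S-value for every term t it contains:
#   S_A(A) = 1;  S_A(t) = max over children t' of t inside DAG_A of
#                          w_e * S_A(t'),
# with edge weights w_e = 0.8 for is-a and 0.6 for part-of. The semantic
# value SV(A) sums the S-values, and two terms are compared through their
# shared ancestors:
#   S_GO(A,B) = sum_{t in T_A ∩ T_B} (S_A(t) + S_B(t)) / (SV(A) + SV(B)).
# Gene-level similarity takes the maximum S_GO over all cross-pairs of the
# two genes' annotation sets (max strategy).

#' Default edge weights for the semantic measure
#'
#' @return Named numeric vector: is_a = 0.8, part_of = 0.6.
#' @export
wang_weights <- function() c(is_a = 0.8, part_of = 0.6)

#' S-values of a term's ancestor graph
#'
#' Computes S_A(t) for every term t in DAG_A (the term A plus all its
#' ancestors reachable through is-a/part-of edges), by upward traversal with
#' the max rule: along each path the edge weights multiply, and a term takes
#' the maximum product over its children within DAG_A.
#'
#' @param term A term id present in `dag`.
#' @param dag A [go_dag()].
#' @param weights Edge weights by relation (default [wang_weights()]).
#' @return Named numeric vector of S-values over T_A, with `S[term] == 1`.
#' @export
s_values <- function(term, dag, weights = wang_weights()) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  e <- dag$edges
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character()
    hits <- e[e$child %in% frontier, , drop = FALSE]
    if (!nrow(hits)) break
    for (r in seq_len(nrow(hits))) {
      val <- weights[[hits$relation[[r]]]] * s[[hits$child[[r]]]]
      p <- hits$parent[[r]]
      if (is.na(s[p]) || val > s[[p]]) {
        s[p] <- val
        nxt <- c(nxt, p)
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Semantic value of a term
#'
#' @inheritParams s_values
#' @return `SV(term)`, the sum of the S-values over the term's ancestor graph.
#' @examples
#' dag <- go_dag(c("A", "R"),
#'               data.frame(child = "A", parent = "R", relation = "is_a"))
#' semantic_value("A", dag)  # 1 + 0.8
#' @export
semantic_value <- function(term, dag, weights = wang_weights()) {
  sum(s_values(term, dag, weights))
}

#' Semantic similarity between two terms
#'
#' @param a,b Term ids present in `dag`.
#' @inheritParams s_values
#' @return `S_GO(a, b)` in \[0, 1\]; 1 when `a == b`, 0 when the ancestor
#'   graphs are disjoint (e.g. different namespaces).
#' @export
term_similarity <- function(a, b, dag, weights = wang_weights()) {
  sa <- s_values(a, dag, weights)
  sb <- s_values(b, dag, weights)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' Functional similarity between two genes (max strategy)
#'
#' The maximum term similarity over all cross-pairs of the two genes'
#' annotation sets. Undefined (`NA`) if either gene has no annotation.
#'
#' @param g1,g2 Gene ids.
#' @param ann An [annotation_set()] (typically the target annotations).
#' @param dag A [go_dag()].
#' @param weights Edge weights by relation.
#' @return Similarity in \[0, 1\], or `NA_real_` for unannotated genes.
#' @export
gene_similarity <- function(g1, g2, ann, dag, weights = wang_weights()) {
  t1 <- gene_terms(ann, g1)
  t2 <- gene_terms(ann, g2)
  if (!length(t1) || !length(t2)) return(NA_real_)
  max(vapply(t1, function(a)
    max(vapply(t2, function(b) term_similarity(a, b, dag, weights),
               numeric(1))), numeric(1)))
}

#' Pairwise gene similarity matrix
#'
#' @param genes Character vector of gene ids.
#' @param ann An [annotation_set()].
#' @param dag A [go_dag()].
#' @param weights Edge weights by relation.
#' @return Symmetric matrix of similarities with unit diagonal for annotated
#'   genes; rows/columns of unannotated genes are `NA`.
#' @export
gene_similarity_matrix <- function(genes, ann, dag, weights = wang_weights()) {
  genes <- unique(genes)
  n <- length(genes)
  # cache S-values per term used
  all_terms <- unique(unlist(lapply(genes, gene_terms, ann = ann)))
  sv_cache <- lapply(stats::setNames(all_terms, all_terms), s_values,
                     dag = dag, weights = weights)
  tsim <- function(a, b) {
    sa <- sv_cache[[a]]; sb <- sv_cache[[b]]
    common <- intersect(names(sa), names(sb))
    sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
  }
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  term_list <- lapply(genes, gene_terms, ann = ann)
  for (i in seq_len(n)) {
    if (!length(term_list[[i]])) next
    S[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      if (!length(term_list[[j]])) next
      s <- max(outer(term_list[[i]], term_list[[j]],
                     Vectorize(tsim, c("a", "b"))))
      S[i, j] <- s; S[j, i] <- s
    }
  }
  S
}

#' Functional clustering of genes by semantic similarity
#'
#' Average-linkage agglomerative clustering on the distance `1 - Sim`, cut at
#' `k` clusters. Genes with undefined similarity (no annotation) are placed
#' at maximal distance (1) from everything.
#'
#' @param sim Similarity matrix from [gene_similarity_matrix()].
#' @param k Number of clusters (1 <= k <= number of genes).
#' @return List: `clusters` (list of gene-id vectors), `membership` (named
#'   integer vector), `tree` (the `hclust` merge tree).
#' @export
functional_cluster <- function(sim, k = 3L) {
  n <- nrow(sim)
  if (k < 1L || k > n) stop("k must be in [1, number of genes]")
  d <- 1 - sim
  d[is.na(d)] <- 1
  diag(d) <- 0
  if (n == 1L) {
    mem <- stats::setNames(1L, rownames(sim))
    return(list(clusters = list(rownames(sim)), membership = mem, tree = NULL))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  mem <- stats::cutree(tree, k = k)
  list(clusters = split(rownames(sim), mem), membership = mem, tree = tree)
}
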