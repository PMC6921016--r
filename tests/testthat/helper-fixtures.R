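# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / brute force) and never call the code paths they check.

two_triangles <- function() {
  gene_network(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to   = c("b", "c", "c", "y", "z", "z")))
}

two_triangles_bridge <- function() {
  gene_network(data.frame(
    from = c("a", "a", "b", "x", "x", "y", "c"),
    to   = c("b", "c", "c", "y", "z", "z", "x")))
}

ring_of_cliques <- function(n_cliques = 4L, size = 4L) {
  edges <- NULL
  for (k in seq_len(n_cliques)) {
    vs <- sprintf("c%d_%d", k, seq_len(size))
    idx <- utils::combn(size, 2L)
    edges <- rbind(edges, data.frame(from = vs[idx[1L, ]], to = vs[idx[2L, ]]))
  }
  bridges <- data.frame(
    from = sprintf("c%d_%d", seq_len(n_cliques), 1L),
    to = sprintf("c%d_%d", c(seq_len(n_cliques)[-1L], 1L), 2L))
  gene_network(rbind(edges, bridges))
}

random_small_graph <- function(n, p = 0.5, weighted = FALSE) {
  vs <- letters[seq_len(n)]
  idx <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(idx)) < p
  if (!any(keep)) keep[sample.int(ncol(idx), 1L)] <- TRUE
  gene_network(data.frame(
    from = vs[idx[1L, keep]], to = vs[idx[2L, keep]],
    weight = if (weighted) sample(1:3, sum(keep), TRUE) else 1),
    vertices = vs)
}

# fast from-scratch modularity for a membership vector (definition, no cache)
oracle_modularity <- function(net, membership) {
  verts <- net$vertices
  A <- matrix(0, length(verts), length(verts), dimnames = list(verts, verts))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, verts); j <- match(net$edges$to, verts)
    A[cbind(i, j)] <- net$edges$weight; A[cbind(j, i)] <- net$edges$weight
  }
  fVV <- sum(A)
  m <- membership[verts]
  intra <- sum(A * outer(m, m, "=="))
  deg <- rowSums(A)
  intra / fVV - sum(tapply(deg, m, sum)^2) / fVV^2
}

# enumerate all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximum-modularity partition (oracle for the greedy search)
oracle_best_partition <- function(net) {
  verts <- net$vertices
  best <- -Inf
  for (p in all_partitions(length(verts))) {
    q <- oracle_modularity(net, stats::setNames(p, verts))
    if (q > best) best <- q
  }
  best
}

# brute-force AUC by concordant-pair counting
oracle_auc <- function(decision, labels) {
  pos <- decision[labels > 0]
  neg <- decision[labels <= 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force Wang S-values: max path-product over all child->parent paths
oracle_s_values <- function(term, dag, weights = wang_weights()) {
  res <- new.env()
  assign(term, 1, envir = res)
  walk <- function(node, prod) {
    up <- dag$edges[dag$edges$child == node, , drop = FALSE]
    for (r in seq_len(nrow(up))) {
      val <- prod * weights[[up$relation[[r]]]]
      p <- up$parent[[r]]
      old <- if (exists(p, envir = res)) get(p, envir = res) else -Inf
      if (val > old) assign(p, val, envir = res)
      walk(p, val)
    }
  }
  walk(term, 1)
  unlist(as.list(res))
}

# tiny nested DAG used by feature and gosim tests
chain_dag <- function() {
  go_dag(c("A", "B", "R"),
         data.frame(child = c("A", "B"), parent = c("B", "R"),
                    relation = c("is_a", "is_a")))
}
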