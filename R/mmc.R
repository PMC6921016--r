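# Maximum modularity clustering (MMC). Modularity of a partition
# C = {C1..Ck} of a weighted undirected graph is
#   Q(C) = sum_i [ f(Ci,Ci)/f(V,V) - dev(Ci)^2 / dev(V)^2 ]
# where f(X,Y) sums edge weights over ordered vertex pairs (each undirected
# edge counted twice within a cluster and in f(V,V)) and dev(Ci) is the total
# degree of the cluster. The search starts from singletons and greedily
# applies the best positive-gain cluster merge (coarsening), then positive-
# gain single-vertex moves (refining), until neither operator increases Q.

adjacency_matrix <- function(net) {
  n <- length(net$vertices)
  A <- matrix(0, n, n, dimnames = list(net$vertices, net$vertices))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$vertices)
    j <- match(net$edges$to, net$vertices)
    A[cbind(i, j)] <- net$edges$weight
    A[cbind(j, i)] <- net$edges$weight
  }
  A
}

as_membership <- function(net, clustering) {
  # accept a named vector or a list of vertex subsets
  if (is.list(clustering)) {
    m <- stats::setNames(rep(seq_along(clustering), lengths(clustering)),
                         unlist(clustering, use.names = FALSE))
  } else m <- clustering
  if (!setequal(names(m), net$vertices) || anyDuplicated(names(m)))
    stop("clustering must partition the network's vertex set")
  m[net$vertices]
}

#' Modularity of a clustering
#'
#' @param net A [gene_network()] with at least one edge.
#' @param clustering Either a named vector (vertex -> cluster label) or a
#'   list of vertex subsets partitioning the network's vertices.
#' @return The modularity Q, in \[-0.5, 1).
#' @examples
#' tri2 <- gene_network(data.frame(
#'   from = c("a","a","b","x","x","y"), to = c("b","c","c","y","z","z")))
#' modularity_q(tri2, list(c("a","b","c"), c("x","y","z"))) # 0.5
#' @export
modularity_q <- function(net, clustering) {
  m <- as_membership(net, clustering)
  A <- adjacency_matrix(net)
  fVV <- sum(A)
  if (fVV == 0) stop("modularity undefined on an edgeless network")
  deg <- rowSums(A)
  q <- 0
  for (cl in unique(m)) {
    idx <- which(m == cl)
    q <- q + sum(A[idx, idx, drop = FALSE]) / fVV - (sum(deg[idx]) / fVV)^2
  }
  q
}

#' Modularity gain of merging two clusters
#'
#' `delta_merge` returns the exact change in Q caused by merging clusters
#' `ci` and `cj`: `2 f(Ci,Cj)/f(V,V) - 2 dev(Ci) dev(Cj)/dev(V)^2`.
#'
#' @param net A [gene_network()].
#' @param clustering Membership (see [modularity_q()]).
#' @param ci,cj Cluster labels to merge.
#' @return The modularity increase (may be negative).
#' @export
delta_merge <- function(net, clustering, ci, cj) {
  m <- as_membership(net, clustering)
  A <- adjacency_matrix(net)
  fVV <- sum(A)
  deg <- rowSums(A)
  ii <- which(m == ci); jj <- which(m == cj)
  if (!length(ii) || !length(jj)) stop("unknown cluster label")
  2 * sum(A[ii, jj, drop = FALSE]) / fVV -
    2 * sum(deg[ii]) * sum(deg[jj]) / fVV^2
}

#' Modularity gain of moving one vertex
#'
#' `delta_move` returns the exact change in Q caused by moving vertex `v`
#' from its cluster Ci to cluster `cj`:
#' `2 (f(v,Cj) - f(v,Ci-v))/f(V,V) - 2 dev(v)(dev(Cj) - dev(Ci-v))/dev(V)^2`.
#' Moving a vertex to its own cluster is the identity (gain 0).
#'
#' @param net A [gene_network()].
#' @param clustering Membership (see [modularity_q()]).
#' @param v Vertex id to move.
#' @param cj Destination cluster label.
#' @return The modularity increase (may be negative).
#' @export
delta_move <- function(net, clustering, v, cj) {
  m <- as_membership(net, clustering)
  if (!v %in% names(m)) stop("unknown vertex: ", v)
  if (m[[v]] == cj) return(0)
  A <- adjacency_matrix(net)
  fVV <- sum(A)
  deg <- rowSums(A)
  vi <- match(v, net$vertices)
  rest_i <- setdiff(which(m == m[[v]]), vi)
  jj <- which(m == cj)
  if (!length(jj)) stop("unknown cluster label: ", cj)
  2 * (sum(A[vi, jj]) - sum(A[vi, rest_i])) / fVV -
    2 * deg[[vi]] * (sum(deg[jj]) - sum(deg[rest_i])) / fVV^2
}

#' Cluster a network by greedy maximum-modularity search
#'
#' Starts from the all-singleton partition. Each outer iteration applies the
#' single best positive-gain merge (ties broken by the lexicographically
#' smallest pair of cluster ids, a cluster's id being its smallest vertex),
#' then sweeps vertices in sorted order applying positive-gain moves until a
#' full sweep changes nothing; the loop ends when neither operator offers a
#' positive gain. Q strictly increases at every accepted operation, so the
#' search terminates. The search is fully deterministic; `seed` is accepted
#' for interface stability but unused.
#'
#' On an edgeless network every vertex is returned as its own cluster and Q
#' is `NA` (modularity is undefined there).
#'
#' @param net A [gene_network()].
#' @param seed Unused (deterministic algorithm).
#' @return Object of class `mmc_clustering`: `membership` (named vector,
#'   cluster labels are each cluster's smallest vertex), `clusters` (list of
#'   vertex subsets), `Q`, and `merges` (data frame logging the accepted
#'   merges with their gains — the coarsening dendrogram).
#' @export
mmc_cluster <- function(net, seed = NULL) {
  verts <- sort(net$vertices)
  merges <- data.frame(step = integer(), cluster_a = character(),
                       cluster_b = character(), dQ = numeric(),
                       Q = numeric(), stringsAsFactors = FALSE)
  if (nrow(net$edges) == 0L) {
    warning("edgeless network: returning singletons, Q undefined")
    m <- stats::setNames(verts, verts)
    return(structure(list(membership = m,
                          clusters = split(verts, m), Q = NA_real_,
                          merges = merges),
                     class = "mmc_clustering"))
  }
  A <- adjacency_matrix(net)[verts, verts]
  fVV <- sum(A)
  deg <- rowSums(A)
  m <- stats::setNames(verts, verts)   # cluster label = smallest member vertex
  eps <- 1e-12

  cluster_id <- function(members) min(members)

  relabel <- function(m) {
    out <- m
    for (lab in unique(m))
      out[m == lab] <- cluster_id(verts[m == lab])
    out
  }

  move_gain_int <- function(mi, vi, id) {
    # id = 0 encodes extraction into a new singleton cluster
    rest_i <- which(mi == mi[[vi]]); rest_i <- rest_i[rest_i != vi]
    base <- sum(A[vi, rest_i]) / fVV - deg[[vi]] * sum(deg[rest_i]) / fVV^2
    if (id == 0L) return(-2 * base)
    jj <- which(mi == id)
    2 * (sum(A[vi, jj]) / fVV - deg[[vi]] * sum(deg[jj]) / fVV^2 - base)
  }

  # Kernighan-Lin style refinement: build a sequence of locally best single
  # moves (any sign, destinations include a fresh singleton cluster), locking
  # each moved vertex, and keep the best prefix; a sweep is accepted only when
  # it strictly increases Q, so the accepted trace stays monotone while
  # individual swaps may pass through downhill states. Cluster identity is
  # tracked by integer ids to keep extractions collision-free.
  refine <- function(m) {
    mi <- as.integer(factor(m, levels = unique(m)))
    n <- length(verts)
    repeat {
      cur <- mi
      cur_gain <- 0
      best_gain <- 0; best_state <- NULL
      locked <- integer()
      repeat {
        step_best <- NULL
        for (vi in setdiff(seq_len(n), locked)) {
          own <- cur[[vi]]
          singleton <- sum(cur == own) == 1L
          targets <- setdiff(sort(unique(cur)), own)
          if (!singleton) targets <- c(targets, 0L)
          for (id in targets) {
            gain <- move_gain_int(cur, vi, id)
            if (is.null(step_best) || gain > step_best$gain + eps)
              step_best <- list(vi = vi, id = id, gain = gain)
          }
        }
        if (is.null(step_best)) break
        cur[[step_best$vi]] <- if (step_best$id == 0L) max(cur) + 1L else
          step_best$id
        locked <- c(locked, step_best$vi)
        cur_gain <- cur_gain + step_best$gain
        if (cur_gain > best_gain + eps) {
          best_gain <- cur_gain
          best_state <- cur
        }
        if (length(locked) == n) break
      }
      if (is.null(best_state)) break
      mi <- best_state
    }
    relabel(stats::setNames(as.character(mi), verts))
  }

  step <- 0L
  repeat {
    labs <- sort(unique(m))
    k <- length(labs)
    best <- list(gain = 0, pair = NULL)
    if (k > 1L) {
      devs <- vapply(labs, function(l) sum(deg[m == l]), numeric(1))
      for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
        ii <- which(m == labs[[a]]); jj <- which(m == labs[[b]])
        gain <- 2 * sum(A[ii, jj]) / fVV - 2 * devs[[a]] * devs[[b]] / fVV^2
        if (gain > best$gain + eps) best <- list(gain = gain, pair = c(a, b))
      }
    }
    if (is.null(best$pair)) {
      m2 <- refine(m)
      if (identical(m2, m)) break
      m <- m2
      next
    }
    la <- labs[[best$pair[[1L]]]]; lb <- labs[[best$pair[[2L]]]]
    m[m == lb] <- la
    id <- cluster_id(verts[m == la])
    m[m == la] <- id
    step <- step + 1L
    m <- refine(m)
    merges <- rbind(merges, data.frame(
      step = step, cluster_a = la, cluster_b = lb, dQ = best$gain,
      Q = modularity_q(net, m), stringsAsFactors = FALSE))
  }
  structure(list(membership = m,
                 clusters = split(names(m), m),
                 Q = modularity_q(net, m), merges = merges),
            class = "mmc_clustering")
}

#' @export
print.mmc_clustering <- function(x, ...) {
  cat("MMC clustering:", length(x$clusters), "clusters, Q =",
      format(x$Q, digits = 6), "\n")
  invisible(x)
}
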