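# Construction of labeled within-complex gene pairs: positives are
# co-complexed pairs that are also physical interactions; negatives are
# co-complexed pairs whose shortest path in the physical network is >= 2
# ("no-less-than-two") or absent ("no-path"), sampled at ratio lambda of
# no-path to no-less-than-two.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

pair_df <- function(a, b) {
  data.frame(geneA = pmin(a, b), geneB = pmax(a, b), stringsAsFactors = FALSE)
}

#' Enumerate co-complexed gene pairs
#'
#' The union, over all complexes, of all unordered pairs of distinct subunits.
#'
#' @param complexes A [complex_set()].
#' @return Data frame with columns `geneA`, `geneB` (canonical order, no
#'   duplicates).
#' @export
cocomplex_pairs <- function(complexes) {
  out <- lapply(unclass(complexes), function(genes) {
    genes <- sort(genes)
    if (length(genes) < 2L) return(NULL)
    idx <- utils::combn(length(genes), 2L)
    data.frame(geneA = genes[idx[1L, ]], geneB = genes[idx[2L, ]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(geneA = character(), geneB = character(),
                      stringsAsFactors = FALSE))
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Positive (direct-contact) pairs
#'
#' Intersects co-complexed pairs with the physical interaction network and
#' removes any curated-indirect pairs in `exclude`. The result is the
#' positive class: pairs that co-occur in a complex and physically interact.
#'
#' @param cocomplex Data frame of co-complexed pairs (`geneA`, `geneB`).
#' @param physical A [gene_network()] of physical interactions.
#' @param exclude Optional data frame of pairs to remove (curated indirect
#'   interactions, or previously used training pairs).
#' @return Data frame `geneA`, `geneB`, `label` (= 1), `provenance`.
#' @export
positive_pairs <- function(cocomplex, physical, exclude = NULL) {
  keys <- pair_key(cocomplex$geneA, cocomplex$geneB)
  edge_keys <- pair_key(physical$edges$from, physical$edges$to)
  keep <- keys %in% edge_keys
  if (!is.null(exclude) && nrow(exclude))
    keep <- keep & !(keys %in% pair_key(exclude$geneA, exclude$geneB))
  out <- cocomplex[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$label <- rep(1L, nrow(out))
  out$provenance <- rep("mapped-positive", nrow(out))
  out
}

#' Classify a pair by shortest-path length in the physical network
#'
#' `"direct"` if the edge exists (path length 1); `"no-path"` if the genes lie
#' in different connected components or either gene is absent from the network
#' (path length taken as infinite); `"no-less-than-two"` if the shortest path
#' has length >= 2. Path length is hop count on the unweighted network.
#'
#' @param pairs Data frame with columns `geneA`, `geneB`.
#' @param physical A [gene_network()].
#' @return Character vector of classes, one per row of `pairs`.
#' @export
path_class <- function(pairs, physical) {
  if (any(pairs$geneA == pairs$geneB)) stop("pair of identical genes")
  g <- as_igraph(physical)
  present_a <- pairs$geneA %in% physical$vertices
  present_b <- pairs$geneB %in% physical$vertices
  cls <- rep("no-path", nrow(pairs))
  both <- present_a & present_b
  if (any(both)) {
    ua <- unique(pairs$geneA[both])
    d <- igraph::distances(g, v = ua, to = unique(pairs$geneB[both]),
                           weights = NA)
    dv <- d[cbind(match(pairs$geneA[both], rownames(d)),
                  match(pairs$geneB[both], colnames(d)))]
    cls[both][dv == 1] <- "direct"
    cls[both][is.finite(dv) & dv >= 2] <- "no-less-than-two"
  }
  cls
}

#' Sampler configuration for negative pairs
#'
#' @param n Number of negative pairs to draw.
#' @param lambda Ratio of no-path to no-less-than-two negatives; `Inf` draws
#'   all negatives from the no-path pool.
#' @param seed RNG seed for reproducible draws.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n, lambda = 4, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(n = as.integer(n), lambda = lambda, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Sample negative (indirect-interaction) pairs
#'
#' Candidates are co-complexed pairs that are not physical edges, split into a
#' no-path pool and a no-less-than-two pool by [path_class()]. The target
#' split is `round(n * lambda / (lambda + 1))` no-path pairs with the
#' remainder from the no-less-than-two pool; if one pool is exhausted the
#' deficit is drawn from the other with a warning. Sampling is uniform without
#' replacement within each pool and reproducible under `cfg$seed`.
#'
#' @param cocomplex Data frame of co-complexed pairs.
#' @param physical A [gene_network()].
#' @param cfg A [sampler_config()].
#' @param exclude Optional data frame of pairs that must not be drawn.
#' @return Data frame `geneA`, `geneB`, `label` (= -1), `provenance`
#'   (`"no-path"` or `"no-less-than-two"`).
#' @export
sample_negatives <- function(cocomplex, physical, cfg, exclude = NULL) {
  keys <- pair_key(cocomplex$geneA, cocomplex$geneB)
  cand <- cocomplex[!(keys %in% pair_key(physical$edges$from,
                                         physical$edges$to)), , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    ck <- pair_key(cand$geneA, cand$geneB)
    cand <- cand[!(ck %in% pair_key(exclude$geneA, exclude$geneB)), , drop = FALSE]
  }
  cls <- path_class(cand, physical)
  pool_np <- cand[cls == "no-path", , drop = FALSE]
  pool_nl <- cand[cls == "no-less-than-two", , drop = FALSE]
  n <- cfg$n
  if (nrow(pool_np) + nrow(pool_nl) < n)
    stop("negative pools too small: no-path=", nrow(pool_np),
         ", no-less-than-two=", nrow(pool_nl), ", requested n=", n)
  n_np <- if (is.infinite(cfg$lambda)) n else
    as.integer(round(n * cfg$lambda / (cfg$lambda + 1)))
  n_nl <- n - n_np
  if (n_np > nrow(pool_np)) {
    warning("no-path pool exhausted (", nrow(pool_np), " < ", n_np,
            "); drawing deficit from no-less-than-two pool")
    n_np <- nrow(pool_np); n_nl <- n - n_np
  }
  if (n_nl > nrow(pool_nl)) {
    warning("no-less-than-two pool exhausted (", nrow(pool_nl), " < ", n_nl,
            "); drawing deficit from no-path pool")
    n_nl <- nrow(pool_nl); n_np <- n - n_nl
  }
  draw <- function(pool, k, tag) {
    if (k == 0L) return(NULL)
    idx <- sample.int(nrow(pool), k)
    out <- pool[idx, , drop = FALSE]
    out$label <- rep(-1L, k)
    out$provenance <- rep(tag, k)
    out
  }
  out <- withr_seed(cfg$seed, {
    rbind(draw(pool_np, n_np, "no-path"),
          draw(pool_nl, n_nl, "no-less-than-two"))
  })
  if (is.null(out))
    out <- data.frame(geneA = character(), geneB = character(),
                      label = integer(), provenance = character())
  rownames(out) <- NULL
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Build a labeled training table of pairs
#'
#' Convenience wrapper chaining [cocomplex_pairs()], [positive_pairs()] and
#' [sample_negatives()]. With `n_neg = NULL` the negative count equals the
#' positive count (balanced classes); if the pools cannot supply that many,
#' positives are subsampled to match the available negatives.
#'
#' @param complexes A [complex_set()].
#' @param physical A [gene_network()].
#' @param lambda,seed Passed to [sampler_config()].
#' @param n_neg Number of negatives, or `NULL` for class balance.
#' @param exclude Optional pairs excluded from both classes.
#' @return Data frame `geneA`, `geneB`, `label`, `provenance`.
#' @export
build_pairs <- function(complexes, physical, lambda = 4, n_neg = NULL,
                        seed = 1L, exclude = NULL) {
  cc <- cocomplex_pairs(complexes)
  pos <- positive_pairs(cc, physical, exclude)
  if (is.null(n_neg)) {
    keys <- pair_key(cc$geneA, cc$geneB)
    pool <- sum(!(keys %in% pair_key(physical$edges$from, physical$edges$to)))
    if (!is.null(exclude) && nrow(exclude)) pool <- pool  # exclusions handled in sampler
    n_neg <- min(nrow(pos), pool)
  }
  neg <- sample_negatives(cc, physical, sampler_config(n_neg, lambda, seed),
                          exclude)
  if (nrow(neg) < nrow(pos)) {
    pos <- withr_seed(seed + 1L,
                      pos[sample.int(nrow(pos), nrow(neg)), , drop = FALSE])
  }
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Write labeled pairs as TSV
#'
#' @param pairs Data frame from [build_pairs()] or friends.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
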