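test_that("modularity reproduces hand-computed partitions", {
  tri2 <- two_triangles()
  expect_equal(modularity_q(tri2, list(c("a", "b", "c"), c("x", "y", "z"))),
               0.5)
  # one cluster holding everything has Q = 0 on any graph
  expect_equal(modularity_q(tri2, list(tri2$vertices)), 0)
  set.seed(4)
  g <- random_small_graph(7, weighted = TRUE)
  expect_equal(modularity_q(g, list(g$vertices)), 0)
  # all singletons on the two triangles: -sum(deg^2)/dev(V)^2 = -1/6
  singles <- as.list(tri2$vertices)
  expect_equal(modularity_q(tri2, singles), -6 * 4 / 144)
  expect_error(modularity_q(gene_network(vertices = c("a", "b")),
                            list(c("a", "b"))), "edgeless")
  expect_error(modularity_q(tri2, list(c("a", "b"))), "partition")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  set.seed(14)
  for (rep in 1:10) {
    g <- random_small_graph(sample(4:8, 1), weighted = TRUE)
    m <- stats::setNames(sample(1:3, length(g$vertices), TRUE), g$vertices)
    expect_equal(modularity_q(g, m),
                 igraph::modularity(as_igraph(g), m[g$vertices],
                                    weights = g$edges$weight),
                 tolerance = 1e-12)
  }
})

test_that("merge and move gains equal from-scratch modularity differences", {
  tri2 <- two_triangles()
  part <- list(c("a", "b", "c"), c("x", "y", "z"))
  m <- stats::setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "x", "y", "z"))
  # merging the triangles: 0 - 2*36/144 = -0.5, consistent with 0.5 -> 0
  expect_equal(delta_merge(tri2, m, 1, 2), -0.5)
  # two vertices joined by the only edge: +0.5 by hand
  pairg <- gene_network(data.frame(from = "u", to = "v"))
  expect_equal(delta_merge(pairg, stats::setNames(1:2, c("u", "v")), 1, 2),
               0.5)
  # identity move
  expect_equal(delta_move(tri2, m, "a", 1), 0)

  set.seed(77)
  for (rep in 1:50) {
    g <- random_small_graph(sample(4:8, 1), weighted = rep %% 2 == 0)
    verts <- g$vertices
    mm <- stats::setNames(sample(1:3, length(verts), TRUE), verts)
    labs <- unique(mm)
    if (length(labs) >= 2) {
      pick <- sample(labs, 2)
      merged <- mm; merged[merged == pick[2]] <- pick[1]
      expect_equal(delta_merge(g, mm, pick[1], pick[2]),
                   oracle_modularity(g, merged) - oracle_modularity(g, mm),
                   tolerance = 1e-12)
      v <- sample(verts, 1)
      others <- setdiff(labs, mm[[v]])
      dest <- others[sample.int(length(others), 1)]
      moved <- mm; moved[[v]] <- dest
      # a move that empties a cluster is still a valid partition afterwards
      expect_equal(delta_move(g, mm, v, dest),
                   oracle_modularity(g, moved) - oracle_modularity(g, mm),
                   tolerance = 1e-12)
    }
  }
  # moving a degree-0 vertex changes nothing
  g0 <- gene_network(data.frame(from = "a", to = "b"),
                     vertices = c("a", "b", "z"))
  m0 <- stats::setNames(c(1, 1, 2), c("a", "b", "z"))
  expect_equal(delta_move(g0, m0, "z", 1), 0)
})

test_that("the greedy search recovers planted structure", {
  # two triangles joined by one bridge: the triangles are optimal
  res <- mmc_cluster(two_triangles_bridge())
  expect_setequal(unname(lapply(res$clusters, sort)),
                  list(c("a", "b", "c"), c("x", "y", "z")))
  # complete graph: a single cluster (Q = 0 is the maximum)
  k5 <- gene_network(data.frame(t(utils::combn(letters[1:5], 2)),
                                stringsAsFactors = FALSE) |>
                       stats::setNames(c("from", "to")))
  res5 <- mmc_cluster(k5)
  expect_length(res5$clusters, 1L)
  expect_equal(res5$Q, 0)
  # ring of four 4-cliques: the cliques
  ring <- ring_of_cliques()
  resr <- mmc_cluster(ring)
  expect_length(resr$clusters, 4L)
  expect_setequal(unname(lapply(resr$clusters,
                                function(cl) sort(sub("_.*", "", cl)))),
                  lapply(sprintf("c%d", 1:4), rep, 4))
  # disjoint cliques (no bridges) are recovered exactly
  cl2 <- gene_network(rbind(
    data.frame(t(utils::combn(c("p", "q", "r"), 2))) |>
      stats::setNames(c("from", "to")),
    data.frame(t(utils::combn(c("s", "t", "u"), 2))) |>
      stats::setNames(c("from", "to"))))
  expect_setequal(unname(lapply(mmc_cluster(cl2)$clusters, sort)),
                  list(c("p", "q", "r"), c("s", "t", "u")))
})

test_that("greedy Q is near the exhaustive optimum on small graphs", {
  set.seed(101)
  for (rep in 1:12) {
    g <- random_small_graph(sample(4:7, 1), p = 0.45, weighted = rep > 6)
    res <- mmc_cluster(g)
    best <- oracle_best_partition(g)
    expect_gte(res$Q, 0.9 * best - 1e-12)
    # never worse than the trivial partitions
    expect_gte(res$Q, max(0, modularity_q(g, as.list(g$vertices))) - 1e-12)
  }
})

test_that("edgeless networks yield singletons with undefined Q", {
  g <- gene_network(vertices = c("a", "b", "c"))
  expect_warning(res <- mmc_cluster(g), "edgeless")
  expect_length(res$clusters, 3L)
  expect_true(is.na(res$Q))
})

test_that("the merge log is a monotone coarsening trace", {
  res <- mmc_cluster(ring_of_cliques())
  expect_true(all(res$merges$dQ > 0))
  expect_true(all(diff(res$merges$Q) > -1e-12))
  expect_equal(res$merges$Q[nrow(res$merges)], res$Q)
})
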