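test_that("S-values follow the weighted max rule on hand-built DAGs", {
  # A is-a R
  d1 <- go_dag(c("A", "R"), data.frame(child = "A", parent = "R",
                                       relation = "is_a"))
  s <- s_values("A", d1)
  expect_equal(s[["A"]], 1)
  expect_equal(s[["R"]], 0.8)
  expect_error(s_values("nope", d1), "unknown term")

  # A part-of P, P is-a R: 0.6 then 0.8 * 0.6
  d2 <- go_dag(c("A", "P", "R"),
               data.frame(child = c("A", "P"), parent = c("P", "R"),
                          relation = c("part_of", "is_a")))
  s2 <- s_values("A", d2)
  expect_equal(s2[["P"]], 0.6)
  expect_equal(s2[["R"]], 0.48)

  # diamond: A is-a X, A part-of Y, X is-a R, Y is-a R -> max path product
  d3 <- go_dag(c("A", "X", "Y", "R"),
               data.frame(child = c("A", "A", "X", "Y"),
                          parent = c("X", "Y", "R", "R"),
                          relation = c("is_a", "part_of", "is_a", "is_a")))
  expect_equal(s_values("A", d3)[["R"]], max(0.8 * 0.8, 0.6 * 0.8))
})

test_that("semantic values sum the ancestor S-values", {
  root_only <- go_dag("R")
  expect_equal(semantic_value("R", root_only), 1)
  d1 <- go_dag(c("A", "R"), data.frame(child = "A", parent = "R",
                                       relation = "is_a"))
  expect_equal(semantic_value("A", d1), 1.8)
  d2 <- go_dag(c("A", "B", "R"),
               data.frame(child = c("A", "B"), parent = c("B", "R"),
                          relation = "is_a"))
  expect_equal(semantic_value("A", d2), 1 + 0.8 + 0.64)
})

test_that("term similarity is symmetric, bounded and exact on siblings", {
  sib <- go_dag(c("A", "B", "R"),
                data.frame(child = c("A", "B"), parent = c("R", "R"),
                           relation = "is_a"))
  expect_equal(term_similarity("A", "A", sib), 1)
  expect_equal(term_similarity("A", "B", sib), (0.8 + 0.8) / (1.8 + 1.8))
  expect_equal(term_similarity("A", "B", sib), term_similarity("B", "A", sib))
  # disjoint components share no ancestors
  disj <- go_dag(c("A", "R1", "B", "R2"),
                 data.frame(child = c("A", "B"), parent = c("R1", "R2"),
                            relation = "is_a"))
  expect_equal(term_similarity("A", "B", disj), 0)
})

test_that("traversal S-values equal brute-force max path products", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(8:14, 1)
    terms <- sprintf("T%02d", seq_len(n))
    child <- character(); parent <- character(); rel <- character()
    for (i in 2:n) {
      pa <- sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))
      child <- c(child, rep(terms[i], length(pa)))
      parent <- c(parent, terms[pa])
      rel <- c(rel, sample(c("is_a", "part_of"), length(pa), TRUE))
    }
    dag <- go_dag(terms, data.frame(child = child, parent = parent,
                                    relation = rel))
    for (t in sample(terms, 3)) {
      s <- s_values(t, dag)
      o <- oracle_s_values(t, dag)
      expect_equal(s[sort(names(s))], o[sort(names(o))], tolerance = 1e-12)
    }
    # bounds and symmetry of the derived term similarity
    ab <- sample(terms, 2)
    s12 <- term_similarity(ab[1], ab[2], dag)
    expect_gte(s12, 0); expect_lte(s12, 1)
    expect_equal(s12, term_similarity(ab[2], ab[1], dag))
  }
})

test_that("gene similarity uses the max strategy over annotation cross-pairs", {
  sib <- go_dag(c("A", "B", "R"),
                data.frame(child = c("A", "B"), parent = c("R", "R"),
                           relation = "is_a"))
  ann <- annotation_set(list(g1 = "A", g2 = "B", g3 = c("A", "R"),
                             shared1 = "A", shared2 = "A",
                             empty = character()), "target")
  expect_equal(gene_similarity("shared1", "shared2", ann, sib), 1)
  expect_equal(gene_similarity("g1", "g2", ann, sib), 4 / 9)
  # exhaustive max over {A,R} x {B}
  expect_equal(gene_similarity("g3", "g2", ann, sib),
               max(term_similarity("A", "B", sib),
                   term_similarity("R", "B", sib)))
  expect_true(is.na(gene_similarity("g1", "empty", ann, sib)))
})

test_that("adding annotations never decreases max-strategy similarity", {
  set.seed(13)
  dag <- generate_world(synthetic_config(n_complexes = 5L), seed = 2L)$dag
  pool <- dag$terms[grepl("^GO:2", dag$terms)]
  base <- sample(pool, 3)
  ann1 <- annotation_set(list(g1 = base, g2 = sample(pool, 3)), "target")
  s1 <- gene_similarity("g1", "g2", ann1, dag)
  for (extra in sample(setdiff(pool, base), 3)) {
    ann2 <- annotation_set(list(g1 = c(base, extra),
                                g2 = ann1$annotations$g2), "target")
    expect_gte(gene_similarity("g1", "g2", ann2, dag), s1 - 1e-12)
  }
})

test_that("the similarity matrix is symmetric with unit diagonal", {
  w <- generate_world(synthetic_config(n_complexes = 8L), seed = 6L)
  cpx <- w$complexes[[which.max(lengths(w$complexes))]][1:6]
  S <- gene_similarity_matrix(cpx, w$target, w$dag)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 6))
  expect_true(all(S >= 0 & S <= 1))
  # matrix entries agree with the pairwise function
  expect_equal(S[1, 2], gene_similarity(cpx[1], cpx[2], w$target, w$dag))
})

test_that("functional clustering recovers planted groups and honors k", {
  sibs <- go_dag(c("A", "B", "R"),
                 data.frame(child = c("A", "B"), parent = c("R", "R"),
                            relation = "is_a"))
  ann <- annotation_set(list(g1 = "A", g2 = "A", g3 = "A",
                             h1 = "B", h2 = "B", h3 = "B"), "target")
  S <- gene_similarity_matrix(c("g1", "g2", "g3", "h1", "h2", "h3"), ann, sibs)
  fc <- functional_cluster(S, k = 2)
  expect_setequal(unname(lapply(fc$clusters, sort)),
                  list(c("g1", "g2", "g3"), c("h1", "h2", "h3")))
  expect_length(functional_cluster(S, k = 1)$clusters, 1L)
  expect_length(functional_cluster(S, k = 6)$clusters, 6L)
  expect_error(functional_cluster(S, k = 7), "k must be")
})
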