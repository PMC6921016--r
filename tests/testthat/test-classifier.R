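# direct evaluation of the penalized objective, for oracle comparisons
pen_obj <- function(w, b, X, y, C) {
  z <- as.numeric(X %*% w) + b
  0.5 * sum(w^2) + C * sum(log1p(exp(-y * z)))
}

test_that("the fitted objective matches a grid-search oracle on a 2-D toy", {
  set.seed(1)
  X <- rbind(c(2, 0), c(1.5, 0.5), c(2, 1), c(1, 0.2),
             c(0, 1.5), c(0.3, 2), c(0.5, 1), c(0, 1))
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  fit <- fit_l2lr(X, y, C = 1, intercept = FALSE)

  # two-stage brute-force grid over the weight plane (never uses the solver)
  grid_min <- function(w1s, w2s) {
    vals <- outer(w1s, w2s, Vectorize(function(a, b)
      pen_obj(c(a, b), 0, X, y, 1)))
    i <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    list(w = c(w1s[i[1]], w2s[i[2]]), val = min(vals))
  }
  g1 <- grid_min(seq(-3, 3, by = 0.05), seq(-3, 3, by = 0.05))
  g2 <- grid_min(seq(g1$w[1] - 0.1, g1$w[1] + 0.1, by = 0.001),
                 seq(g1$w[2] - 0.1, g1$w[2] + 0.1, by = 0.001))
  expect_lt(abs(fit$objective - g2$val), 1e-4)
  expect_lte(fit$objective, g2$val + 1e-8)   # solver at least as good as grid
})

test_that("regularization dominates as C -> 0 and duplication halves C", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  y <- ifelse(X[, 1] + rnorm(20, sd = 0.3) > 0, 1, -1)
  tiny <- fit_l2lr(X, y, C = 1e-8, intercept = FALSE)
  expect_lt(sqrt(sum(tiny$weights^2)), 1e-4)

  # duplicating every instance doubles the loss term: same optimum as 2C
  dup <- fit_l2lr(rbind(X, X), c(y, y), C = 0.5, intercept = TRUE)
  orig <- fit_l2lr(X, y, C = 1, intercept = TRUE)
  expect_equal(dup$weights, orig$weights, tolerance = 1e-5)
  expect_equal(dup$intercept, orig$intercept, tolerance = 1e-5)
})

test_that("the solver agrees with glmnet ridge at the matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(X[, 1] - X[, 2] + rnorm(n, sd = 0.5) > 0, 1, -1)
  C <- 2
  fit <- fit_l2lr(X, y, C = C)
  # glmnet: (1/n) logloss + (lambda/2)||w||^2  ==  Eq-3 objective / (nC)
  gn <- glmnet::glmnet(X, factor(y, levels = c(-1, 1)), family = "binomial",
                       alpha = 0, lambda = 1 / (n * C), standardize = FALSE,
                       thresh = 1e-14, maxit = 1e6)
  expect_equal(unname(fit$weights), as.numeric(gn$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, as.numeric(gn$a0), tolerance = 1e-3)
})

test_that("single-class input and non-positive C are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_l2lr(X, rep(1, 5)), "single class")
  expect_error(fit_l2lr(X, c(1, 1, 1, -1, -1), C = 0), "C must be")
})

# a deterministic model for decision tests: one weight per term, no data
toy_model <- function(weights, intercept = 0) {
  structure(list(weights = weights, intercept = intercept, C = 1,
                 index = structure(names(weights), class = "term_index"),
                 n_instances = 0L, objective = NA_real_),
            class = "contact_model")
}

test_that("the combined decision takes the larger-magnitude instance", {
  model <- toy_model(c(t1 = 2, t2 = -2))
  tgt <- annotation_set(list(a = "t1", b = "t1", c = "t2", d = "t2"), "target")
  hom <- annotation_set(list(a = "t2", b = character(), c = "t1",
                             d = character()), "homolog")
  # pair (a,b): target shares t1 (m_T strongly +), homolog weak
  d <- decide_pairs(model, data.frame(geneA = "a", geneB = "b"), tgt, hom)
  expect_equal(d$decision, d$m_target)
  expect_equal(d$label, 1L)
  # pair (c,d): target shares t2 -> negative margin dominates
  d2 <- decide_pairs(model, data.frame(geneA = "c", geneB = "d"), tgt, hom)
  expect_equal(d2$decision, d2$m_target)
  expect_equal(d2$label, -1L)
  # the combined value always equals one of the two instance values
  w <- generate_world(synthetic_config(n_complexes = 10L), seed = 33L)
  pairs <- suppressWarnings(build_pairs(w$complexes, w$interactome, seed = 5L))
  m <- train_contact_model(pairs, w$target, w$homolog)
  dd <- decide_pairs(m, pairs, w$target, w$homolog)
  ok <- !is.na(dd$decision)
  expect_true(all(dd$decision[ok] == dd$m_target[ok] |
                  dd$decision[ok] == dd$m_homolog[ok]))
})

test_that("delta filters weak predictions into the undetermined class", {
  model <- toy_model(c(t1 = 0.3, t2 = 5))
  tgt <- annotation_set(list(a = "t1", b = "t1"), "target")
  hom <- annotation_set(list(a = character(), b = character()), "homolog")
  pr <- data.frame(geneA = "a", geneB = "b")
  m <- decide_pairs(model, pr, tgt, hom)$decision     # plogis(0.6)-0.5 = 0.146
  expect_equal(decide_pairs(model, pr, tgt, hom, delta = 0.1)$label, 1L)
  expect_equal(decide_pairs(model, pr, tgt, hom, delta = 0.2)$label, 0L)
  # both instances empty: unpredictable at any delta
  un <- decide_pairs(model, data.frame(geneA = "x", geneB = "y"), tgt, hom)
  expect_equal(un$status, "unpredictable")
  expect_equal(un$label, 0L)
})

test_that("raising delta never adds predicted edges", {
  w <- generate_world(synthetic_config(n_complexes = 10L), seed = 8L)
  pairs <- suppressWarnings(build_pairs(w$complexes, w$interactome, seed = 5L))
  model <- train_contact_model(pairs, w$target, w$homolog)
  cpx <- w$complexes[[which.max(lengths(w$complexes))]]
  prev <- Inf
  for (delta in c(0, 0.05, 0.1, 0.2, 0.4, 0.6)) {
    net <- predict_complex_network(cpx, model, w$target, w$homolog, delta)
    expect_lte(nrow(net$edges), prev)
    prev <- nrow(net$edges)
  }
  # delta beyond the margin range leaves every subunit isolated
  expect_equal(prev, 0L)
})

test_that("predict_complex_network returns the labeled-positive edge set", {
  model <- toy_model(c(t1 = 10), intercept = -5)
  tgt <- annotation_set(stats::setNames(rep(list("t1"), 4),
                                        c("a", "b", "c", "d")), "target")
  hom <- annotation_set(list(), "homolog")
  net <- predict_complex_network(c("a", "b", "c", "d"), model, tgt, hom)
  expect_equal(nrow(net$edges), 6L)   # complete graph K4
  expect_true(all(net$edges$weight > 0))
  expect_error(predict_complex_network(c("a", "b"), model, tgt, hom),
               ">= 3 subunits")
})

test_that("model serialization round-trips weights and metadata", {
  model <- toy_model(c("GO:1" = 0.5, "GO:2" = -1.25), intercept = 0.75)
  f <- withr::local_tempfile()
  write_contact_model(model, f)
  back <- read_contact_model(f)
  expect_equal(back$weights, model$weights)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$C, model$C)
})
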