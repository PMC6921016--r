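# End-to-end pipeline: labeled pair construction -> cross-validation ->
# final model -> per-complex network prediction -> connection-degree triage
# -> substructure inference (maximum-modularity clustering for partially
# connected complexes, GO-semantic functional clustering for fully connected
# ones) -> optional evaluation against reference sub-complexes.

#' Run the full direct-contact / substructure pipeline
#'
#' @param complexes A [complex_set()].
#' @param interactome A [gene_network()] of physical interactions.
#' @param target,homolog [annotation_set()] objects.
#' @param dag A [go_dag()]; required for the functional-clustering branch.
#' @param lambda No-path : no-less-than-two negative sampling ratio.
#' @param n_neg Negative count (`NULL` = balance the classes).
#' @param C Penalty parameter of the logistic model.
#' @param delta Decision-confidence threshold (0 = keep every prediction).
#' @param full_threshold Connection degree from which a complex counts as
#'   fully connected.
#' @param k Cluster count for functional clustering: a single integer applied
#'   to every fully connected complex (capped at its subunit count), or a
#'   named vector keyed by complex id.
#' @param xi Jaccard threshold for the evaluation against `reference`.
#' @param seed Seed driving negative sampling and fold assignment.
#' @param cv_folds Cross-validation folds (0 skips cross-validation).
#' @param exclude Optional pairs excluded from training (e.g. curated
#'   indirect interactions or an independent test set).
#' @param reference Optional list of reference sub-complex gene vectors for
#'   [cluster_prf()] evaluation.
#' @return List of class `subcomplex_run`: `pairs`, `cv`, `model`,
#'   `networks`, `profiles`, `fractions`, `clusters` (named list per complex:
#'   list of gene vectors), `method` (per complex: `"mmc"`, `"functional"` or
#'   `"isolated"`), `evaluation` (if `reference` given), `params`.
#' @export
run_pipeline <- function(complexes, interactome, target, homolog, dag = NULL,
                         lambda = 4, n_neg = NULL, C = 1, delta = 0,
                         full_threshold = 0.95, k = 3L, xi = 0.5,
                         seed = 1L, cv_folds = 5L, exclude = NULL,
                         reference = NULL) {
  pairs <- build_pairs(complexes, interactome, lambda = lambda, n_neg = n_neg,
                       seed = seed, exclude = exclude)
  cv <- if (cv_folds >= 2L)
    cv_contact_model(pairs, target, homolog, k = cv_folds, C = C,
                     seed = seed, delta = delta)
  model <- train_contact_model(pairs, target, homolog, C = C)

  networks <- lapply(unclass(complexes), predict_complex_network,
                     model = model, target = target, homolog = homolog,
                     delta = delta)
  profiles <- complex_profiles(networks, full_threshold)
  fractions <- triage_fractions(profiles)

  clusters <- list(); method <- character()
  k_of <- function(cid, N) {
    kk <- if (!is.null(names(k))) k[[cid]] else k
    min(as.integer(kk), N)
  }
  for (r in seq_len(nrow(profiles))) {
    cid <- profiles$complex[[r]]
    subunits <- complexes[[cid]]
    cat_r <- profiles$category[[r]]
    if (cat_r == "partially") {
      cl <- mmc_cluster(networks[[cid]])
      clusters[[cid]] <- unname(cl$clusters)
      method[[cid]] <- "mmc"
    } else if (cat_r == "fully") {
      if (is.null(dag)) {
        method[[cid]] <- "skipped"
        next
      }
      sim <- gene_similarity_matrix(subunits, target, dag)
      fc <- functional_cluster(sim, k = k_of(cid, length(subunits)))
      clusters[[cid]] <- unname(fc$clusters)
      method[[cid]] <- "functional"
    } else {
      method[[cid]] <- "isolated"
    }
  }

  evaluation <- NULL
  if (!is.null(reference) && length(clusters))
    evaluation <- cluster_prf(do.call(c, unname(clusters)), reference, xi)

  structure(list(pairs = pairs, cv = cv, model = model, networks = networks,
                 profiles = profiles, fractions = fractions,
                 clusters = clusters, method = method,
                 evaluation = evaluation,
                 params = list(lambda = lambda, C = C, delta = delta,
                               full_threshold = full_threshold, k = k,
                               xi = xi, seed = seed, cv_folds = cv_folds)),
            class = "subcomplex_run")
}

#' @export
print.subcomplex_run <- function(x, ...) {
  cat("subcomplex pipeline run\n")
  cat("  pairs:", sum(x$pairs$label == 1L), "positive /",
      sum(x$pairs$label == -1L), "negative\n")
  if (!is.null(x$cv))
    cat("  CV AUC: combined", round(x$cv$auc[["combined"]], 4),
        "| target", round(x$cv$auc[["target"]], 4),
        "| homolog", round(x$cv$auc[["homolog"]], 4), "\n")
  cat("  triage: ", paste(sprintf("%s %.1f%%", names(x$fractions),
                                  100 * x$fractions), collapse = ", "), "\n")
  cat("  clustered complexes:", length(x$clusters), "\n")
  if (!is.null(x$evaluation))
    cat(sprintf("  vs reference: precision %.3f recall %.3f F %.3f\n",
                x$evaluation$precision, x$evaluation$recall,
                x$evaluation$fscore))
  invisible(x)
}
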