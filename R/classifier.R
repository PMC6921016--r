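# L2-regularized logistic regression for direct-contact prediction. The
# model minimizes 0.5 * w'w + C * sum_i log(1 + exp(-y_i * (w'x_i + b)))
# over the stacked target and homolog instances of the training pairs
# (all-zero instances are skipped; the intercept b is unpenalized). At
# prediction time each instance yields a signed confidence m = P(+1|x) - 0.5
# in (-0.5, 0.5); the pair's combined decision value is the instance value of
# larger magnitude (target wins ties) and the final label is +1 if m > delta,
# -1 if -m > delta, undetermined otherwise.

logloss <- function(t) {
  # log(1 + exp(-t)) computed stably
  ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t)))
}

l2lr_objective <- function(theta, X, y, C, intercept = TRUE) {
  p <- ncol(X)
  w <- theta[seq_len(p)]
  b <- if (intercept) theta[p + 1L] else 0
  z <- as.numeric(X %*% w) + b
  0.5 * sum(w * w) + C * sum(logloss(y * z))
}

l2lr_gradient <- function(theta, X, y, C, intercept = TRUE) {
  p <- ncol(X)
  w <- theta[seq_len(p)]
  b <- if (intercept) theta[p + 1L] else 0
  z <- as.numeric(X %*% w) + b
  s <- y * stats::plogis(-y * z)       # y * sigma(-y z)
  gw <- w - C * as.numeric(Matrix::crossprod(X, s))
  if (intercept) c(gw, -C * sum(s)) else gw
}

#' Train the direct-contact model on an instance matrix
#'
#' Low-level fitting routine: given an instance matrix and labels, returns the
#' weight vector minimizing the penalized logistic loss
#' \eqn{\frac12 \omega^\top\omega + C\sum_i \log(1+e^{-y_i\omega^\top x_i})}
#' to solver tolerance (L-BFGS-B on the exact objective and gradient).
#'
#' @param X Instance matrix (dense or `dgCMatrix`), one row per instance.
#' @param y Labels in \{-1, +1\}.
#' @param C Penalty parameter (> 0) multiplying the data term.
#' @param intercept Include an unpenalized intercept (default `TRUE`).
#' @param tol Convergence tolerance on the objective (`factr`-scaled).
#' @return List with `weights`, `intercept`, `objective`, `C`, `converged`.
#' @export
fit_l2lr <- function(X, y, C = 1, intercept = TRUE, tol = 1e-10) {
  if (C <= 0) stop("C must be > 0")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  p <- ncol(X)
  theta0 <- numeric(p + as.integer(intercept))
  fit <- stats::optim(theta0, fn = l2lr_objective, gr = l2lr_gradient,
                      X = X, y = y, C = C, intercept = intercept,
                      method = "L-BFGS-B",
                      control = list(maxit = 1000L, factr = tol / .Machine$double.eps))
  w <- fit$par[seq_len(p)]
  names(w) <- colnames(X)
  list(weights = w,
       intercept = if (intercept) fit$par[p + 1L] else 0,
       objective = fit$value, C = C, converged = fit$convergence == 0L)
}

#' Train the direct-contact model on labeled pairs
#'
#' Each pair contributes two training examples with the pair's label: its
#' target instance and its homolog instance (all-zero instances are skipped).
#' The term index defaults to the union of the training genes' target and
#' homolog terms (see [build_term_index()]).
#'
#' @param pairs Data frame with columns `geneA`, `geneB`, `label` (-1/+1).
#' @param target,homolog [annotation_set()] objects.
#' @param index Optional `term_index`; built from the training genes if `NULL`.
#' @param C Penalty parameter (default 1).
#' @param intercept Include an unpenalized intercept.
#' @return Object of class `contact_model`: `weights`, `intercept`, `C`,
#'   `index`, `n_instances`, `objective`.
#' @export
train_contact_model <- function(pairs, target, homolog, index = NULL, C = 1,
                                intercept = TRUE) {
  if (is.null(index))
    index <- build_term_index(c(pairs$geneA, pairs$geneB), target, homolog)
  XT <- pair_feature_matrix(pairs, target, index)
  XH <- pair_feature_matrix(pairs, homolog, index)
  keepT <- Matrix::rowSums(XT) > 0
  keepH <- Matrix::rowSums(XH) > 0
  X <- rbind(XT[keepT, , drop = FALSE], XH[keepH, , drop = FALSE])
  y <- c(pairs$label[keepT], pairs$label[keepH])
  fit <- fit_l2lr(X, y, C = C, intercept = intercept)
  structure(list(weights = fit$weights, intercept = fit$intercept, C = C,
                 index = index, n_instances = length(y),
                 objective = fit$objective),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat("Direct-contact model: |G| =", length(x$index), "terms, C =", x$C,
      ",", x$n_instances, "training instances\n")
  invisible(x)
}

instance_margin <- function(model, X) {
  # signed confidence m = P(+1|x) - 0.5; NA for all-zero instances
  z <- as.numeric(X %*% model$weights) + model$intercept
  m <- stats::plogis(z) - 0.5
  m[Matrix::rowSums(abs(X)) == 0] <- NA_real_
  m
}

#' Score pairs and assign final labels
#'
#' Computes the target-instance and homolog-instance confidences, combines
#' them (larger magnitude wins, target wins ties; a missing instance defers
#' to the other) and applies the delta filter: label +1 if the combined value
#' m exceeds `delta`, -1 if -m exceeds `delta`, otherwise `0` = undetermined.
#' Pairs with both instances all-zero get status `"unpredictable"`.
#'
#' @param model A `contact_model`.
#' @param pairs Data frame with columns `geneA`, `geneB`.
#' @param target,homolog [annotation_set()] objects.
#' @param delta Confidence threshold in \[0, 0.5) (default 0: no filtering).
#' @param setting Which instances feed the decision: `"combined"` (default),
#'   `"target"` or `"homolog"` only.
#' @return Data frame: `geneA`, `geneB`, `m_target`, `m_homolog`, `decision`,
#'   `label` (+1 / -1 / 0 = undetermined), `status` (`"ok"`/`"unpredictable"`).
#' @export
decide_pairs <- function(model, pairs, target, homolog, delta = 0,
                         setting = c("combined", "target", "homolog")) {
  setting <- match.arg(setting)
  mT <- instance_margin(model, pair_feature_matrix(pairs, target, model$index))
  mH <- instance_margin(model, pair_feature_matrix(pairs, homolog, model$index))
  comb <- switch(setting,
    combined = ifelse(is.na(mT), mH,
               ifelse(is.na(mH), mT,
               ifelse(abs(mT) >= abs(mH), mT, mH))),
    target = mT,
    homolog = mH)
  label <- ifelse(is.na(comb), 0L,
           ifelse(comb > delta, 1L, ifelse(-comb > delta, -1L, 0L)))
  data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
             m_target = mT, m_homolog = mH, decision = comb,
             label = label,
             status = ifelse(is.na(comb), "unpredictable", "ok"),
             stringsAsFactors = FALSE)
}

#' Predict the physical subunit network of one complex
#'
#' Scores every unordered subunit pair and returns the network of pairs
#' labeled +1, weighted by the magnitude of the combined decision value.
#' Undetermined and unpredictable pairs yield no edge.
#'
#' @param subunits Character vector of >= 3 subunit gene ids.
#' @param model A `contact_model`.
#' @param target,homolog [annotation_set()] objects.
#' @param delta Confidence threshold (see [decide_pairs()]).
#' @return A [gene_network()] over the subunits.
#' @export
predict_complex_network <- function(subunits, model, target, homolog,
                                    delta = 0) {
  subunits <- unique(subunits)
  if (length(subunits) < 3L) stop("complex must have >= 3 subunits")
  cc <- cocomplex_pairs(complex_set(list(cx = subunits), min_size = 1L))
  dec <- decide_pairs(model, cc, target, homolog, delta)
  pos <- dec[dec$label == 1L, , drop = FALSE]
  gene_network(data.frame(from = pos$geneA, to = pos$geneB,
                          weight = abs(pos$decision)),
               vertices = subunits)
}

#' Cross-validate the direct-contact model
#'
#' k-fold cross-validation over pairs (both instances of a pair stay in the
#' same fold). Within each fold the term index is rebuilt from the training
#' genes only, so test-time terms outside it are discarded as they would be
#' in a real run. ROC-AUC is reported for the three evaluation settings:
#' combined decision values, target instances alone and homolog instances
#' alone.
#'
#' @param pairs Labeled pair table (`label` in -1/+1).
#' @param target,homolog [annotation_set()] objects.
#' @param k Number of folds (default 5).
#' @param C Penalty parameter.
#' @param seed Seed controlling the fold assignment.
#' @param delta Threshold used for the confusion-matrix metrics.
#' @return List: `auc` (named: combined/target/homolog), `metrics` (from
#'   [class_metrics()] on pooled combined-setting predictions), `coverage`
#'   (fraction of pairs with a determinate label), `folds`.
#' @export
cv_contact_model <- function(pairs, target, homolog, k = 5L, C = 1,
                             seed = 1L, delta = 0) {
  n <- nrow(pairs)
  fold <- withr_seed(seed, sample(rep_len(seq_len(k), n)))
  dec_all <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- pairs[fold != f, , drop = FALSE]
    te <- pairs[fold == f, , drop = FALSE]
    model <- train_contact_model(tr, target, homolog, C = C)
    d <- lapply(c("combined", "target", "homolog"), function(s)
      decide_pairs(model, te, target, homolog, delta, setting = s)$decision)
    dec_all[[f]] <- data.frame(label = te$label, combined = d[[1L]],
                               target = d[[2L]], homolog = d[[3L]])
  }
  dec <- do.call(rbind, dec_all)
  auc <- vapply(c("combined", "target", "homolog"), function(s) {
    ok <- !is.na(dec[[s]])
    roc_auc(dec[[s]][ok], dec$label[ok])
  }, numeric(1))
  pred <- ifelse(is.na(dec$combined), 0L,
          ifelse(dec$combined > delta, 1L,
          ifelse(-dec$combined > delta, -1L, 0L)))
  det <- pred != 0L
  M <- confusion_matrix(dec$label[det], pred[det])
  list(auc = auc, metrics = class_metrics(M), coverage = mean(det),
       folds = fold)
}

#' Serialize / restore a contact model as TSV
#'
#' The file has a `# key value` metadata header (intercept, C) followed by
#' `term<TAB>weight` rows.
#'
#' @param model A `contact_model`.
#' @param path File path.
#' @return `read_contact_model` returns a `contact_model`.
#' @export
write_contact_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# intercept", format(model$intercept, digits = 17)),
               paste("# C", format(model$C, digits = 17))), con)
  utils::write.table(data.frame(term = names(model$weights),
                                weight = unname(model$weights)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_model
#' @export
read_contact_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^# ", lines)]
  get_meta <- function(key) {
    as.numeric(sub(paste0("^# ", key, " "), "",
                   meta[grepl(paste0("^# ", key, " "), meta)]))
  }
  body <- strsplit(lines[!grepl("^#", lines) & nzchar(lines)], "\t")
  w <- stats::setNames(as.numeric(vapply(body, `[[`, character(1), 2L)),
                       vapply(body, `[[`, character(1), 1L))
  structure(list(weights = w, intercept = get_meta("intercept"),
                 C = get_meta("C"),
                 index = structure(names(w), class = "term_index"),
                 n_instances = NA_integer_, objective = NA_real_),
            class = "contact_model")
}
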