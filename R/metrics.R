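# Evaluation metrics: confusion-matrix precision/sensitivity/MCC in the
# generic L-class form, rank-based ROC-AUC on decision values, and
# Jaccard-threshold matching metrics for comparing a predicted set of
# sub-complexes with a reference partition.

#' Build a 2x2 confusion matrix
#'
#' Row i, column j counts instances of true class i classified as class j.
#' Class order is (+1, -1): class 1 is the positive (direct-contact) class.
#'
#' @param truth,pred Vectors of -1/+1 labels (undetermined predictions should
#'   be removed before calling; they are excluded from the matrix).
#' @return A 2x2 integer matrix with dimnames `c("+1","-1")`.
#' @export
confusion_matrix <- function(truth, pred) {
  lev <- c(1, -1)
  M <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  M <- matrix(as.integer(M), 2, 2, dimnames = list(c("+1", "-1"), c("+1", "-1")))
  M
}

#' Per-class and overall metrics from a confusion matrix
#'
#' For each class l, with p_l = M\[l,l\], r_l the off-class instances
#' predicted as l, s_l the class-l instances predicted elsewhere and q_l the
#' remaining counts: PR_l = p_l/(p_l+r_l), SE_l = p_l/(p_l+s_l) and
#' MCC_l = (p_l q_l - r_l s_l) / sqrt((p_l+r_l)(p_l+s_l)(q_l+r_l)(q_l+s_l)).
#' Overall accuracy is the trace fraction and the overall MCC uses the sums
#' p, q, r, s across classes. Zero denominators yield `NA` (undefined), not 0.
#'
#' @param M Square confusion matrix (class i -> predicted j), any L >= 2.
#' @return List: `per_class` data frame (`class`, `PR`, `SE`, `MCC`), `Acc`,
#'   `MCC`.
#' @export
class_metrics <- function(M) {
  M <- as.matrix(M)
  L <- nrow(M)
  if (L != ncol(M) || L < 2L) stop("confusion matrix must be square, L >= 2")
  if (sum(M) == 0) stop("confusion matrix has no instances")
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  p <- q <- r <- s <- numeric(L)
  for (l in seq_len(L)) {
    p[l] <- M[l, l]
    q[l] <- sum(M[-l, -l, drop = FALSE])
    r[l] <- sum(M[-l, l])
    s[l] <- sum(M[l, -l])
  }
  mcc_l <- safe_div(p * q - r * s, sqrt((p + r) * (p + s) * (q + r) * (q + s)))
  per_class <- data.frame(
    class = if (!is.null(rownames(M))) rownames(M) else as.character(seq_len(L)),
    PR = safe_div(p, p + r), SE = safe_div(p, p + s), MCC = mcc_l,
    stringsAsFactors = FALSE)
  P <- sum(p); Qs <- sum(q); R <- sum(r); S <- sum(s)
  list(per_class = per_class,
       Acc = sum(diag(M)) / sum(M),
       MCC = safe_div(P * Qs - R * S,
                      sqrt((P + R) * (P + S) * (Qs + R) * (Qs + S))))
}

#' F1 score of the positive class
#'
#' @param PR,SE Precision and sensitivity of the positive class.
#' @return `2 PR SE / (PR + SE)`; 0 when both are 0.
#' @export
f1_score <- function(PR, SE) {
  if (is.na(PR) || is.na(SE)) return(NA_real_)
  if (PR + SE == 0) return(0)
  2 * PR * SE / (PR + SE)
}

#' Rank-based ROC-AUC
#'
#' AUC computed from midranks of the decision values: equal to the
#' probability that a random positive outranks a random negative, with ties
#' counting one half.
#'
#' @param decision Numeric decision values (larger = more positive).
#' @param labels Labels; the positive class is `+1` (anything `> 0`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(decision, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(decision)           # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Jaccard index of two gene sets
#'
#' @param P,C Character vectors (sets).
#' @return `|P ∩ C| / |P ∪ C|`.
#' @export
jaccard <- function(P, C) {
  P <- unique(P); C <- unique(C)
  u <- length(union(P, C))
  if (u == 0L) return(NA_real_)
  length(intersect(P, C)) / u
}

#' Cluster-matching precision, recall and F-score
#'
#' A predicted cluster matches a reference cluster when their Jaccard index
#' is at least `xi`. Precision is the fraction of predicted clusters matching
#' some reference cluster; recall the fraction of reference clusters matched
#' by some prediction; F the harmonic mean.
#'
#' @param predicted,reference Lists of gene-id vectors.
#' @param xi Jaccard threshold in (0, 1\] (default 0.5).
#' @return List: `precision`, `recall`, `fscore`.
#' @export
cluster_prf <- function(predicted, reference, xi = 0.5) {
  if (xi <= 0 || xi > 1) stop("xi must be in (0, 1]")
  if (!length(predicted) || !length(reference))
    stop("need at least one predicted and one reference cluster")
  J <- outer(seq_along(predicted), seq_along(reference),
             Vectorize(function(i, j) jaccard(predicted[[i]], reference[[j]])))
  precision <- mean(apply(J >= xi, 1L, any))
  recall <- mean(apply(J >= xi, 2L, any))
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, fscore = f)
}
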