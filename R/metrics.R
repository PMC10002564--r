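# Multi-class evaluation: top-1 accuracy, micro-averaged AUC and AUPR over
# the flattened label-indicator matrix, macro-averaged F1 over per-class
# scores, and a per-event one-vs-rest table.

#' ROC AUC of a score vector
#'
#' Rank-based (Mann-Whitney) with midranks for ties; `NA` when either class
#' is absent.
#'
#' @param y Binary labels (0/1 or logical).
#' @param s Numeric scores.
#' @return AUC in `[0, 1]` or `NA`.
#' @export
roc_auc <- function(y, s) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral `sum_k (R_k - R_{k-1}) P_k` over distinct score
#' thresholds in decreasing order, with tied scores grouped; `NA` when there
#' are no positives.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]` or `NA`.
#' @export
pr_auc <- function(y, s) {
  y <- as.numeric(y)
  P <- sum(y == 1)
  if (P == 0L) return(NA_real_)
  o <- order(s, decreasing = TRUE)
  ys <- y[o]
  ss <- s[o]
  boundary <- which(c(diff(ss) != 0, TRUE))   # last index of each tie group
  tp <- cumsum(ys)[boundary]
  np <- boundary                               # predictions above threshold
  prec <- tp / np
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Multi-class metrics for DDI event prediction
#'
#' Computes top-1 accuracy (argmax with ties broken towards the lowest
#' index), micro-averaged AUC and AUPR over the flattened `n x Nl`
#' label-indicator and probability matrices, macro-averaged F1 (unweighted
#' mean of per-class F1, with F1 = 0 for classes whose precision + recall is
#' zero), and per-event one-vs-rest AUC/AUPR.
#'
#' @param truth Integer vector of true event indices (0-based).
#' @param probs `n x Nl` matrix of class probabilities (rows sum to 1).
#' @param Nl Number of classes (default `ncol(probs)`).
#' @return A `ddi_metrics` object: list with `acc`, `auc_micro`,
#'   `aupr_micro`, `f1_macro`, `per_event` (tibble), `n`.
#' @export
ddi_metrics <- function(truth, probs, Nl = ncol(probs)) {
  stopifnot(length(truth) == nrow(probs), Nl >= 1)
  n <- length(truth)
  if (n == 0L) stop("cannot compute metrics on an empty set")
  pred <- apply(probs, 1L, which.max) - 1L
  acc <- mean(pred == truth)
  Y <- matrix(0, n, Nl)
  Y[cbind(seq_len(n), truth + 1L)] <- 1
  auc_micro <- roc_auc(as.vector(Y), as.vector(probs))
  aupr_micro <- pr_auc(as.vector(Y), as.vector(probs))
  f1 <- vapply(seq_len(Nl) - 1L, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  per_event <- tibble::tibble(
    event = seq_len(Nl) - 1L,
    n_true = vapply(seq_len(Nl), function(k) sum(truth == k - 1L), numeric(1)),
    auc = vapply(seq_len(Nl), function(k) roc_auc(Y[, k], probs[, k]),
                 numeric(1)),
    aupr = vapply(seq_len(Nl), function(k) pr_auc(Y[, k], probs[, k]),
                  numeric(1)),
    f1 = f1)
  structure(list(acc = acc, auc_micro = auc_micro, aupr_micro = aupr_micro,
                 f1_macro = mean(f1), per_event = per_event, n = n),
            class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf(
    "<ddi_metrics> n = %d | ACC %.4f | micro-AUPR %.4f | micro-AUC %.4f | macro-F1 %.4f\n",
    x$n, x$acc, x$aupr_micro, x$auc_micro, x$f1_macro))
  invisible(x)
}
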