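# Multiclass evaluation suite: confusion matrix, accuracy, macro F1,
# multiclass Matthews correlation coefficient, macro sensitivity and
# specificity, and one-vs-rest AUC-ROC.
#
# Zero-denominator conventions (documented, the literature is split): an
# undefined per-class F1/sensitivity/specificity contributes 0 to the
# macro mean; an MCC with zero denominator is 0.

#' Confusion matrix
#'
#' @param labels integer true classes in 1..n_classes.
#' @param predictions integer predicted classes in 1..n_classes.
#' @param n_classes number of classes.
#' @return n_classes x n_classes integer matrix, rows = truth,
#'   columns = prediction.
#' @export
confusion <- function(labels, predictions, n_classes) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length", call. = FALSE)
  if (any(labels < 1 | labels > n_classes) ||
      any(predictions < 1 | predictions > n_classes))
    stop("labels out of range 1..n_classes", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels))
    cm[labels[i], predictions[i]] <- cm[labels[i], predictions[i]] + 1L
  cm
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    stop("confusion matrix must be square and non-empty", call. = FALSE)
}

#' Overall accuracy: trace over total
#' @param cm confusion matrix (rows = truth).
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Macro-averaged one-vs-rest F1
#' @param cm confusion matrix.
#' @export
f1_macro <- function(cm) {
  check_cm(cm)
  mean(vapply(seq_len(nrow(cm)), function(k) {
    x <- ovr_counts(cm, k)
    denom <- 2 * x["tp"] + x["fp"] + x["fn"]
    if (denom == 0) 0 else unname(2 * x["tp"] / denom)
  }, numeric(1)))
}

#' Macro-averaged sensitivity (recall)
#' @param cm confusion matrix.
#' @export
sensitivity_macro <- function(cm) {
  check_cm(cm)
  mean(vapply(seq_len(nrow(cm)), function(k) {
    x <- ovr_counts(cm, k)
    if (x["tp"] + x["fn"] == 0) 0 else unname(x["tp"] / (x["tp"] + x["fn"]))
  }, numeric(1)))
}

#' Macro-averaged specificity
#' @param cm confusion matrix.
#' @export
specificity_macro <- function(cm) {
  check_cm(cm)
  mean(vapply(seq_len(nrow(cm)), function(k) {
    x <- ovr_counts(cm, k)
    if (x["tn"] + x["fp"] == 0) 0 else unname(x["tn"] / (x["tn"] + x["fp"]))
  }, numeric(1)))
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance form over the confusion matrix,
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, `p_k` the column sums and `t_k` the
#' row sums. Reduces to the familiar binary closed form; 1 when every
#' sample is correct, -1 in the binary all-wrong case; 0 when the
#' denominator vanishes.
#'
#' @param cm confusion matrix.
#' @export
mcc <- function(cm) {
  check_cm(cm)
  cm <- cm * 1.0
  s <- sum(cm)
  c0 <- sum(diag(cm))
  p <- colSums(cm)
  t <- rowSums(cm)
  num <- c0 * s - sum(p * t)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) 0 else num / den
}

#' Macro one-vs-rest AUC-ROC
#'
#' Per class, the rank-based AUC (Mann-Whitney with midranks for ties) of
#' that class's probability column against the binary class indicator;
#' averaged over classes present in `labels`. Classes absent from the
#' labels are skipped with a warning.
#'
#' @param probs n x K probability matrix.
#' @param labels integer labels in 1..K.
#' @export
auc_roc_ovr <- function(probs, labels) {
  K <- ncol(probs)
  if (nrow(probs) != length(labels))
    stop("probs rows must align with labels", call. = FALSE)
  aucs <- numeric(0)
  for (k in seq_len(K)) {
    pos <- labels == k
    if (!any(pos) || all(pos)) {
      warning("class ", k, " absent from labels (or its complement); skipped")
      next
    }
    r <- rank(probs[, k])
    n1 <- sum(pos); n0 <- sum(!pos)
    u <- sum(r[pos]) - n1 * (n1 + 1) / 2
    aucs <- c(aucs, u / (n1 * n0))
  }
  mean(aucs)
}

#' Full metrics report
#'
#' One record with the six headline metrics in the standard column order:
#' Accuracy, F1-score, MCC, Sensitivity, Specificity, AUC-ROC.
#'
#' @param cm confusion matrix.
#' @param probs optional probability matrix for AUC (NA when omitted).
#' @param labels labels aligned with `probs`.
#' @return a one-row data.frame.
#' @export
metrics_report <- function(cm, probs = NULL, labels = NULL) {
  auc <- if (is.null(probs)) NA_real_ else auc_roc_ovr(probs, labels)
  data.frame(
    Accuracy = accuracy(cm),
    `F1-score` = f1_macro(cm),
    MCC = mcc(cm),
    Sensitivity = sensitivity_macro(cm),
    Specificity = specificity_macro(cm),
    `AUC-ROC` = auc,
    check.names = FALSE)
}
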