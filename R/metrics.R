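#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' \eqn{P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)} over all positive/negative
#' score pairs, which equals the trapezoidal ROC area.  Deterministic
#' and invariant to strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param y_true Binary labels (0/1) with both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_rank(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
auc_rank <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("length mismatch", call. = FALSE)
  if (!all(y_true %in% c(0, 1))) stop("`y_true` must be coded 0/1", call. = FALSE)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Confusion counts and derived rates for binary predictions, with class
#' 1 as the positive class (in the cancer-classification setting, label
#' 1 is the tumor class; sensitivity and specificity swap if the coding
#' is reversed).  A rate whose denominator is zero (e.g. sensitivity
#' with no positive samples) is reported as `NA`, never silently 0.
#'
#' @param y_true Binary labels (0/1).
#' @param y_pred Binary predictions (0/1).
#' @param scores Optional numeric scores for the AUC; if omitted, AUC is
#'   `NA`.
#' @return List of class `metrics_report` with `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels and predictions must be coded 0/1", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, y_true)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(y_true),
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 auc = auc),
            class = "metrics_report")
}

#' Support-recovery metrics
#'
#' Compares the nonzero pattern of an estimated coefficient vector with
#' the true one, elementwise: TP counts coordinates nonzero in both, FN
#' truly nonzero but estimated zero, FP truly zero but estimated
#' nonzero, TN zero in both.  Beta-sensitivity = TP / (TP + FN) is the
#' fraction of true features recovered; beta-specificity = TN / (TN +
#' FP) the fraction of noise features correctly rejected.  Zero
#' denominators yield `NA`.
#'
#' @param beta_true True coefficient vector.
#' @param beta_hat Estimated coefficient vector, same length.
#' @param tol Magnitude below or at which an estimate counts as zero
#'   (default 0: exact zeros, which the thresholding operators produce).
#' @return List of class `metrics_report` with `beta_tp`, `beta_fp`,
#'   `beta_tn`, `beta_fn`, `beta_sensitivity`, `beta_specificity`.
#' @examples
#' support_metrics(c(2, 2, 0, 0), c(3, 0, 1, 0))
#' @export
support_metrics <- function(beta_true, beta_hat, tol = 0) {
  if (length(beta_true) != length(beta_hat)) stop("length mismatch", call. = FALSE)
  s_true <- beta_true != 0
  s_hat <- abs(beta_hat) > tol
  tp <- sum(s_true & s_hat)
  fn <- sum(s_true & !s_hat)
  fp <- sum(!s_true & s_hat)
  tn <- sum(!s_true & !s_hat)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(beta_tp = tp, beta_fp = fp, beta_tn = tn, beta_fn = fn,
                 beta_sensitivity = rate(tp, tp + fn),
                 beta_specificity = rate(tn, tn + fp)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.4f", v)
  if (!is.null(x$accuracy)) {
    cat("accuracy ", fmt(x$accuracy), "  sensitivity ", fmt(x$sensitivity),
        "  specificity ", fmt(x$specificity), "  AUC ", fmt(x$auc), "\n",
        sep = "")
    cat("confusion: TP ", x$tp, " FP ", x$fp, " TN ", x$tn, " FN ", x$fn,
        "\n", sep = "")
  }
  if (!is.null(x$beta_sensitivity)) {
    cat("beta-sensitivity ", fmt(x$beta_sensitivity),
        "  beta-specificity ", fmt(x$beta_specificity),
        "  (TP ", x$beta_tp, " FP ", x$beta_fp, " TN ", x$beta_tn,
        " FN ", x$beta_fn, ")\n", sep = "")
  }
  invisible(x)
}
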