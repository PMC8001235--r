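#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention that any zero factor in the denominator yields 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts.
#' @return MCC in \[-1, 1\].
#' @export
#' @examples
#' mcc(10, 10, 0, 0)  # 1
#' mcc(50, 40, 10, 15)
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' MCC of predicted vs true binary labels
#' @param pred,truth Binary vectors of equal length.
#' @return MCC in \[-1, 1\].
#' @export
mcc_labels <- function(pred, truth) {
  pred <- as_binary(pred, "pred"); truth <- as_binary(truth, "truth")
  mcc(sum(pred == 1 & truth == 1), sum(pred == 0 & truth == 0),
      sum(pred == 1 & truth == 0), sum(pred == 0 & truth == 1))
}

#' Area under the ROC curve with the full curve
#'
#' AUC is computed as the Mann-Whitney probability that a positive sample is
#' ranked above a negative one, ties counting one half.
#'
#' @param scores Continuous prediction scores.
#' @param y Binary labels (both classes present).
#' @return List with `auc` and `curve` (tibble `threshold, fpr, tpr`).
#' @export
roc_auc <- function(scores, y) {
  y <- as_binary(y)
  check_both_classes(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0),
    fpr = vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0)
  )
  list(auc = auc, curve = curve)
}

#' t-based 95% confidence interval over cross-validation fold metrics
#'
#' @param fold_metrics Numeric vector of at least 2 per-fold values.
#' @return Tibble `mean, lower, upper, n`.
#' @export
cv_confidence_interval <- function(fold_metrics) {
  n <- length(fold_metrics)
  if (n < 2) {
    abort_edison("At least 2 fold metrics are required.",
                 "metric_insufficient_data_error")
  }
  m <- mean(fold_metrics)
  half <- qt(0.975, n - 1) * sd(fold_metrics) / sqrt(n)
  tibble::tibble(mean = m, lower = m - half, upper = m + half, n = n)
}

#' McNemar comparison of two classifiers on the same test set
#'
#' Builds the 2x2 table of correct/incorrect agreement; with at least 25
#' discordant pairs the continuity-corrected chi-squared
#' `(|b - c| - 1)^2 / (b + c)` is used, otherwise the exact two-sided
#' binomial test. No discordance gives p = 1.
#'
#' @param pred_a,pred_b Binary predictions of the two models.
#' @param y_test True labels of the shared test samples.
#' @return List `statistic, p_value, b, c, method` where `b` counts samples
#'   only model A got right and `c` samples only model B got right.
#' @export
mcnemar_compare <- function(pred_a, pred_b, y_test) {
  pred_a <- as_binary(pred_a, "pred_a")
  pred_b <- as_binary(pred_b, "pred_b")
  y_test <- as_binary(y_test, "y_test")
  stopifnot(length(pred_a) == length(y_test),
            length(pred_b) == length(y_test))
  ok_a <- pred_a == y_test
  ok_b <- pred_b == y_test
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = cc,
                method = "no discordance"))
  }
  if (b + cc < 25) {
    p <- binom.test(b, b + cc, 0.5)$p.value
    list(statistic = NA_real_, p_value = unname(p), b = b, c = cc,
         method = "exact binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    list(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = cc, method = "continuity-corrected chi-squared")
  }
}
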