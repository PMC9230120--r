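# Evaluation suite: confusion-matrix metrics, MCC, threshold-sweep ROC and
# precision-recall curves, stratified cross-validation, and Pearson
# correlation. Positive class = 1 = high confidence throughout.

check_binary <- function(y) {
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  invisible(y)
}

#' Confusion matrix and threshold metrics
#'
#' Undefined ratios (zero denominator) are reported as 0 with a warning.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return List with `confusion` (named counts TP, FP, TN, FN),
#'   `accuracy` (percent), `precision`, `recall`, `f1`.
#' @export
confusion_and_scores <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  check_binary(y_true); check_binary(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator); reported as 0"); 0 }
    else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (zero denominator); reported as 0"); 0
  } else 2 * precision * recall / (precision + recall)
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = 100 * (tp + tn) / length(y_true),
       precision = precision, recall = recall, f1 = f1)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; any zero factor
#' in the denominator gives 0 (the standard convention for degenerate
#' predictions).
#'
#' @param confusion Named counts with elements TP, FP, TN, FN.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  tp <- as.numeric(confusion[["TP"]]); fp <- as.numeric(confusion[["FP"]])
  tn <- as.numeric(confusion[["TN"]]); fn <- as.numeric(confusion[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

sweep_counts <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  data.frame(threshold = s[grp_end],
             tp = cumsum(y)[grp_end],
             fp = cumsum(1 - y)[grp_end])
}

#' ROC curve and AUROC
#'
#' Threshold sweep over the unique scores (ties grouped), area by the
#' trapezoid rule. Points start at (0, 0) and end at (1, 1).
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  check_binary(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  sw <- sweep_counts(y_true, scores)
  fpr <- c(0, sw$fp / n0, 1)
  tpr <- c(0, sw$tp / n1, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, sw$threshold, -Inf)),
       auc = auc)
}

#' Precision-recall curve and average precision
#'
#' Threshold sweep with ties grouped; average precision is the
#' step-weighted sum `sum((R_k - R_{k-1}) * P_k)` (the usual
#' average-precision score, not a trapezoid).
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric scores.
#' @return List with `points` (data.frame `recall`, `precision`,
#'   `threshold`) and `average_precision`.
#' @export
pr_ap <- function(y_true, scores) {
  check_binary(y_true)
  n1 <- sum(y_true == 1)
  if (n1 == 0 || n1 == length(y_true)) stop("both classes must be present")
  sw <- sweep_counts(y_true, scores)
  recall <- sw$tp / n1
  precision <- sw$tp / (sw$tp + sw$fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision,
                           threshold = sw$threshold),
       average_precision = ap)
}

#' Stratified k-fold cross-validation accuracy
#'
#' Folds are disjoint, cover all rows, and keep per-fold class
#' proportions within one row. Reports the mean and sample standard
#' deviation of held-out-fold accuracy, in percent.
#'
#' @param table Labelled feature table.
#' @param params Hyperparameter list for [train_classifier()].
#' @param k Number of folds (each class must have >= k rows).
#' @param seed Integer seed.
#' @return Named vector `c(mean, sd)` in percent.
#' @export
cross_validate <- function(table, params = list(), k = 10L, seed = 42L) {
  stopifnot(k >= 2)
  counts <- table(table$label)
  if (any(counts < k)) stop("each class needs at least k = ", k, " rows")
  folds <- stratified_folds(table$label, k, seed)
  res <- cv_accuracy(table, params, folds, seed)
  c(mean = 100 * res[["mean"]], sd = 100 * res[["sd"]])
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of length >= 3 with nonzero variance.
#' @return List with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Evaluate a fitted classifier on a held-out table
#'
#' Bundles the whole evaluation suite for one model/test-set pair.
#'
#' @param model A `gene_classifier`.
#' @param test Labelled feature table.
#' @return List of class `evaluation_report`: `confusion`, `accuracy`
#'   (percent), `precision`, `recall`, `f1`, `mcc`, `auroc`,
#'   `average_precision`, `roc_points`, `pr_points`.
#' @export
evaluate_classifier <- function(model, test) {
  pred <- predict(model, test)
  cs <- confusion_and_scores(test$label, pred$label)
  roc <- roc_auc(test$label, pred$probability)
  pr <- pr_ap(test$label, pred$probability)
  structure(c(cs, list(mcc = mcc(cs$confusion),
                       auroc = roc$auc,
                       average_precision = pr$average_precision,
                       roc_points = roc$points,
                       pr_points = pr$points)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (positive class = high confidence)\n")
  cat(sprintf("  accuracy: %.2f%%  F1: %.4f  MCC: %.4f\n",
              x$accuracy, x$f1, x$mcc))
  cat(sprintf("  AUROC: %.4f  average precision: %.4f\n",
              x$auroc, x$average_precision))
  cm <- x$confusion
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]]))
  invisible(x)
}
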