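#' Binary confusion matrix
#'
#' Counts TP/FP/TN/FN after designating one class as positive; every other
#' label counts as negative.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels, same length.
#' @param positive The positive class; default the first sorted class of
#'   `y_true`.
#' @return A `confusion_matrix` list with `TP`, `FP`, `TN`, `FN` and
#'   `positive`.
#' @export
confusion <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(positive)) positive <- sort(unique(y_true))[1]
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  out <- list(TP = tp, FP = fp, TN = tn, FN = fn, positive = positive)
  class(out) <- "confusion_matrix"
  out
}

#' Construct a confusion matrix from counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts, total > 0.
#' @param positive Positive-class name (informational).
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FP, TN, FN, positive = "positive") {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  out <- list(TP = TP, FP = FP, TN = TN, FN = FN, positive = positive)
  class(out) <- "confusion_matrix"
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/total; precision = TP/(TP+FP);
#' sensitivity = recall = TP/(TP+FN); F1 = harmonic mean of precision and
#' recall = 2TP/(2TP+FP+FN). A 0/0 denominator yields 0 with a warning
#' rather than NaN, keeping benchmark tables stable.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report` list with `accuracy`, `precision`, `recall`,
#'   `sensitivity`, `f1`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("0/0 in ", what, "; defined as 0")
      0
    } else {
      num / den
    }
  }
  accuracy <- (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN)
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- safe_div(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN, "f1")
  out <- list(accuracy = accuracy, precision = precision, recall = recall,
              sensitivity = recall, f1 = f1)
  class(out) <- "metrics_report"
  out
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over the unique scores (predict positive when
#' score >= threshold) and returns the (FPR, TPR) path with trapezoidal
#' area under it.
#'
#' @param y_true Binary labels.
#' @param scores Real-valued scores, higher = more positive.
#' @param positive Positive-class label; default first sorted class.
#' @return List with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  if (is.null(positive)) positive <- sort(unique(y_true))[1]
  is_pos <- y_true == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(scores >= t & is_pos) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !is_pos) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thresholds, auc = auc)
}

#' Precision-recall curve
#'
#' Threshold sweep analogous to [roc_curve()]; the zero-prediction point
#' (recall 0) uses precision 1 by convention.
#'
#' @inheritParams roc_curve
#' @return List with `recall`, `precision`, `thresholds`.
#' @export
pr_curve <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  if (is.null(positive)) positive <- sort(unique(y_true))[1]
  is_pos <- y_true == positive
  if (sum(is_pos) == 0 || sum(!is_pos) == 0) {
    stop("PR curve requires both classes present")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thresholds, function(t) {
    pred_pos <- scores >= t
    tp <- sum(pred_pos & is_pos)
    c(recall = tp / sum(is_pos),
      precision = if (sum(pred_pos) == 0) 1 else tp / sum(pred_pos))
  }, numeric(2))
  list(recall = c(0, pts["recall", ]),
       precision = c(1, pts["precision", ]),
       thresholds = c(Inf, thresholds))
}

#' Two-proportion Z test on two classifiers' accuracies
#'
#' Pooled two-proportion statistic
#' Z = (a - b) / sqrt(2 p (1 - p) / n) with p = (a + b) / 2, two-sided
#' p-value, and the 95% significance call |Z| > 1.96.
#'
#' @param acc_a,acc_b Accuracies in [0, 1] measured on the same test size.
#' @param n Test-set size.
#' @return A `comparison_test` list with `z_statistic`, `p_value`,
#'   `significant_95`.
#' @export
z_test <- function(acc_a, acc_b, n) {
  stopifnot(acc_a >= 0, acc_a <= 1, acc_b >= 0, acc_b <= 1, n > 0)
  p_bar <- (acc_a + acc_b) / 2
  if (p_bar %in% c(0, 1)) {
    z <- if (acc_a == acc_b) 0 else sign(acc_a - acc_b) * Inf
  } else {
    z <- (acc_a - acc_b) / sqrt(2 * p_bar * (1 - p_bar) / n)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  out <- list(z_statistic = z, p_value = p,
              significant_95 = abs(z) > z_critical())
  class(out) <- "comparison_test"
  out
}

#' The two-sided 95% normal critical value
#' @return `qnorm(0.975)`, approximately 1.96.
#' @export
z_critical <- function() qnorm(0.975)

#' The chi-squared df = 1, alpha = 0.05 critical value
#' @return `qchisq(0.95, 1)`, approximately 3.841.
#' @export
chi2_critical <- function() qchisq(0.95, df = 1)

#' Chi-squared test on two classifiers' correct/incorrect counts
#'
#' 2 x 2 contingency table (classifier x correct/incorrect), df = 1,
#' no continuity correction. A degenerate margin (both classifiers all
#' correct, or all incorrect) yields a statistic of 0.
#'
#' @param correct_a,correct_b Correctly classified counts, 0..n.
#' @param n Test-set size for each classifier.
#' @return A `comparison_test` list with `chi2_statistic`, `p_value`,
#'   `significant_95`.
#' @export
chi2_test <- function(correct_a, correct_b, n) {
  stopifnot(correct_a >= 0, correct_a <= n, correct_b >= 0, correct_b <= n)
  tab <- rbind(c(correct_a, n - correct_a),
               c(correct_b, n - correct_b))
  if (any(colSums(tab) == 0)) {
    stat <- 0
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expected)^2 / expected)
  }
  out <- list(chi2_statistic = stat,
              p_value = pchisq(stat, df = 1, lower.tail = FALSE),
              significant_95 = stat > chi2_critical())
  class(out) <- "comparison_test"
  out
}

#' Random (unstratified) hold-out split
#'
#' Shuffles the indices and sends `floor(train_fraction * n)` of them to
#' the training set, the rest to the test set. Deliberately unstratified.
#'
#' @param n Number of samples, >= 2.
#' @param train_fraction Training share; default 0.6 (a 60/40 split).
#' @param seed Integer seed.
#' @return A `split_plan` list with `train`, `test`, `seed`.
#' @export
holdout_split <- function(n, train_fraction = 0.6, seed = 1) {
  if (n < 2) stop("hold-out split requires n >= 2")
  set.seed(stage_seed(seed, 0))
  perm <- sample.int(n)
  n_train <- floor(train_fraction * n)
  out <- list(train = sort(perm[seq_len(n_train)]),
              test = sort(perm[-seq_len(n_train)]),
              seed = seed)
  class(out) <- "split_plan"
  out
}

#' Random k-fold split
#'
#' Shuffles the indices into k disjoint, exhaustive folds whose sizes
#' differ by at most one.
#'
#' @param n Number of samples.
#' @param k Fold count, <= n; default 5.
#' @param seed Integer seed.
#' @return A `split_plan` list with `folds` (list of index vectors).
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
  set.seed(stage_seed(seed, 0))
  perm <- sample.int(n)
  sizes <- rep(floor(n / k), k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  folds <- lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
  out <- list(folds = folds, k = k, seed = seed)
  class(out) <- "split_plan"
  out
}
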