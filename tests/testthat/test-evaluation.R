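test_that("confusion counts agree with a per-pair tally oracle", {
  y <- rep(c("pos", "neg"), 5)
  expect_equal(confusion(y, y, positive = "pos")[c("FP", "FN")],
               list(FP = 0L, FN = 0L), ignore_attr = TRUE)

  set.seed(51)
  yt <- sample(c("pos", "neg"), 20, replace = TRUE)
  yp <- sample(c("pos", "neg"), 20, replace = TRUE)
  cm <- confusion(yt, yp, positive = "pos")
  tally <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in seq_along(yt)) {
    key <- if (yt[i] == "pos" && yp[i] == "pos") "TP"
    else if (yt[i] != "pos" && yp[i] == "pos") "FP"
    else if (yt[i] != "pos" && yp[i] != "pos") "TN"
    else "FN"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]), tally)
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 20)
  expect_error(confusion(yt, yp[-1]), "equal length")
})

test_that("metrics apply the confusion-matrix formulas exactly", {
  # the benchmark's reported test matrix: 35 TP, 22 TN, 13 FP, 0 FN (n = 70)
  cm <- confusion_counts(TP = 35, FP = 13, TN = 22, FN = 0)
  m <- metrics(cm)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$accuracy, 57 / 70)
  expect_equal(m$precision, 35 / 48)
  expect_equal(m$f1, 2 * 35 / (2 * 35 + 13 + 0))

  # precision = recall = p implies f1 = p
  cm2 <- confusion_counts(TP = 6, FP = 2, TN = 10, FN = 2)
  m2 <- metrics(cm2)
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)

  # 0/0 denominators yield 0 with a warning, not NaN
  cm3 <- confusion_counts(TP = 0, FP = 0, TN = 5, FN = 0)
  w <- capture_warnings(m3 <- metrics(cm3))
  expect_match(w, "0/0", all = TRUE)
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)

  # identity predictions give accuracy 1 for any mixed label vector
  set.seed(52)
  for (rep in 1:5) {
    y <- sample(c("a", "b"), 15, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(suppressWarnings(metrics(confusion(y, y)))$accuracy, 1)
  }
})

test_that("ROC endpoints behave and AUC equals pairwise concordance", {
  y <- c("pos", "pos", "neg", "neg")
  expect_equal(roc_curve(y, c(0.9, 0.8, 0.2, 0.1), positive = "pos")$auc, 1)
  expect_equal(roc_curve(y, c(0.1, 0.2, 0.8, 0.9), positive = "pos")$auc, 0)
  expect_error(roc_curve(rep("pos", 4), runif(4)), "both classes")

  # concordance oracle across small instances, including tied scores
  set.seed(53)
  for (n in 3:12) {
    for (rep in 1:8) {
      y <- sample(c("pos", "neg"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
      got <- roc_curve(y, scores, positive = "pos")$auc
      expect_equal(got, auc_concordance(y, scores, "pos"), tolerance = 1e-12)
    }
  }
})

test_that("ROC AUC matches pROC on a moderate case", {
  set.seed(54)
  y <- sample(c("pos", "neg"), 40, replace = TRUE)
  scores <- runif(40) + 0.5 * (y == "pos")
  got <- roc_curve(y, scores, positive = "pos")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("PR curve matches naive per-threshold recomputation", {
  y <- c("pos", "neg", "pos", "pos", "neg", "neg", "pos", "neg")
  s <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.3, 0.2, 0.1)
  pr <- pr_curve(y, s, positive = "pos")
  # recall reaches 1 when everything is predicted positive
  expect_equal(pr$recall[length(pr$recall)], 1)
  for (i in seq_along(pr$thresholds)[-1]) {
    t <- pr$thresholds[i]
    pred <- s >= t
    tp <- sum(pred & y == "pos")
    expect_equal(pr$recall[i], tp / sum(y == "pos"))
    expect_equal(pr$precision[i], tp / sum(pred))
  }
  # perfect ranking keeps precision at 1 for all achieved recalls
  perfect <- pr_curve(c("pos", "pos", "neg", "neg"), c(4, 3, 2, 1),
                      positive = "pos")
  expect_true(all(perfect$precision[perfect$thresholds >= 3] == 1))
})

test_that("two-proportion Z test follows the pooled formula", {
  expect_equal(z_test(0.8, 0.8, 50)$z_statistic, 0)
  expect_equal(z_test(0.9, 0.7, 100)$z_statistic,
               -z_test(0.7, 0.9, 100)$z_statistic)
  # hand-computed pooled arithmetic
  p_bar <- (0.9 + 0.7) / 2
  want <- (0.9 - 0.7) / sqrt(2 * p_bar * (1 - p_bar) / 100)
  zt <- z_test(0.9, 0.7, 100)
  expect_equal(zt$z_statistic, want)
  expect_equal(zt$p_value, 2 * pnorm(-abs(want)))
  expect_true(zt$significant_95)
  # degenerate pooled proportions give a well-defined zero
  expect_equal(z_test(1, 1, 10)$z_statistic, 0)
  expect_equal(z_test(0, 0, 10)$z_statistic, 0)
  # maximally different accuracies still pool to p = 1/2
  expect_equal(z_test(1, 0, 10)$z_statistic, 1 / sqrt(2 * 0.25 / 10))
})

test_that("chi-squared test matches hand-expanded expected counts", {
  expect_equal(chi2_test(40, 40, 50)$chi2_statistic, 0)
  # (90, 70, 100): hand-expanded 2x2 computation
  tab <- rbind(c(90, 10), c(70, 30))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  want <- sum((tab - expected)^2 / expected)
  got <- chi2_test(90, 70, 100)
  expect_equal(got$chi2_statistic, want)
  expect_true(got$significant_95)
  # independent oracle: stats::chisq.test without continuity correction
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(got$chi2_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  # degenerate margins give 0
  expect_equal(chi2_test(50, 50, 50)$chi2_statistic, 0)
})

test_that("comparison tests are invariant under classifier relabeling", {
  zt_ab <- z_test(0.85, 0.6, 80)
  zt_ba <- z_test(0.6, 0.85, 80)
  expect_equal(zt_ab$z_statistic, -zt_ba$z_statistic)
  expect_equal(zt_ab$p_value, zt_ba$p_value)
  expect_equal(chi2_test(68, 48, 80)$chi2_statistic,
               chi2_test(48, 68, 80)$chi2_statistic)
})

test_that("hold-out splits are disjoint, exhaustive and seed-stable", {
  sp <- holdout_split(10, seed = 1)
  expect_length(sp$train, 6)
  expect_length(sp$test, 4)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(holdout_split(10, seed = 1), sp)
  expect_false(identical(holdout_split(10, seed = 2)$train, sp$train))
  expect_error(holdout_split(1), "n >= 2")
})

test_that("k-fold splits partition with near-equal fold sizes", {
  sp <- kfold_split(10, k = 5, seed = 3)
  expect_equal(lengths(sp$folds), rep(2, 5))
  expect_setequal(unlist(sp$folds), 1:10)

  sp12 <- kfold_split(12, k = 5, seed = 3)
  expect_equal(sort(lengths(sp12$folds), decreasing = TRUE),
               c(3, 3, 2, 2, 2))
  expect_setequal(unlist(sp12$folds), 1:12)
  expect_error(kfold_split(3, k = 5), "exceeds sample count")
})
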