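test_that("confusion counts match a per-sample loop tally", {
  expect_equal(unclass(confusion_counts(c(1, 0), c(0.9, 0.1)))[1:4],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  # threshold 0 predicts everything positive
  cc0 <- confusion_counts(c(1, 0, 1), c(0, 0.2, 0.8), threshold = 0)
  expect_equal(cc0$TN + cc0$FN, 0)
  set.seed(21)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200)
  cc <- confusion_counts(labels, scores, 0.4)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:200) {
    pred <- scores[i] >= 0.4
    if (pred && labels[i] == 1) tp <- tp + 1
    if (!pred && labels[i] == 0) tn <- tn + 1
    if (pred && labels[i] == 0) fp <- fp + 1
    if (!pred && labels[i] == 1) fn <- fn + 1
  }
  expect_equal(unclass(cc)[1:4], list(TP = tp, TN = tn, FP = fp, FN = fn),
               ignore_attr = TRUE)
  expect_error(confusion_counts(c(1, 0), 0.5), "equal length")
})

test_that("Sn, Sp, Acc and MCC follow their confusion-matrix formulas", {
  m <- metrics_from_confusion(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(unlist(m), c(sn = 1, sp = 1, acc = 1, mcc = 1))
  m <- metrics_from_confusion(list(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.7)
  expect_equal(m$mcc, 10 / sqrt(600))
  # degenerate: everything predicted negative
  m <- metrics_from_confusion(list(TP = 0, TN = 5, FP = 0, FN = 3))
  expect_equal(m$sn, 0)
  expect_equal(m$mcc, 0)
})

test_that("metric formulas agree with brute force on random confusions", {
  set.seed(33)
  for (i in 1:200) {
    cts <- as.list(sample(0:10000, 4, replace = TRUE))
    names(cts) <- c("TP", "TN", "FP", "FN")
    if (sum(unlist(cts)) == 0) cts$TP <- 1
    m <- metrics_from_confusion(cts)
    o <- o_metrics(cts$TP, cts$TN, cts$FP, cts$FN)
    for (k in c("sn", "sp", "acc", "mcc"))
      expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
    # accuracy is the prevalence-weighted combination of Sn and Sp
    P <- cts$TP + cts$FN; N <- cts$TN + cts$FP
    expect_equal(m$acc, (P * m$sn + N * m$sp) / (P + N))
    # MCC is invariant under swapping TP<->TN and FP<->FN
    m2 <- metrics_from_confusion(list(TP = cts$TN, TN = cts$TP,
                                      FP = cts$FN, FN = cts$FP))
    expect_equal(m$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("ROC-AUC equals the all-pairs statistic and is rank-invariant", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(17)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)          # rounded scores force ties
    a <- roc_auc(labels, scores)
    expect_equal(a, o_auc_pairs(labels, scores), tolerance = 1e-12)
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(roc_auc(labels, plogis(5 * scores - 2)), a,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  labels <- rbinom(150, 1, 0.3)
  scores <- runif(150)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
})

test_that("PR-AUC matches an exhaustive threshold sweep and F1 its formula", {
  expect_equal(pr_auc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1.0)
  expect_equal(f1_score(list(TP = 3, FP = 0, FN = 0)), 1.0)
  expect_equal(f1_score(list(TP = 3, FP = 1, FN = 2)), 6 / 9)
  expect_equal(f1_score(list(TP = 0, FP = 0, FN = 0)), 0)
  set.seed(23)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.3))
    scores <- round(runif(n), 2)
    expect_equal(pr_auc(labels, scores), o_pr_auc_sweep(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("classification_metrics assembles a consistent report", {
  set.seed(29)
  labels <- rbinom(80, 1, 0.4)
  scores <- runif(80)
  m <- classification_metrics(labels, scores, threshold = 0.35)
  cc <- confusion_counts(labels, scores, 0.35)
  expect_equal(m$f1, f1_score(cc))
  expect_equal(m$auc, roc_auc(labels, scores))
  expect_true(all(unlist(m[c("sn", "sp", "acc", "auc", "f1", "pr_auc")]) >= 0))
  expect_true(m$mcc >= -1 && m$mcc <= 1)
  expect_output(print(m), "MCC")
})
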