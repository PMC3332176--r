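mk_gt <- function() {
  gt <- matrix(0, 10, 10)
  gt[1, 1:10] <- 1          # 10 lesion, 90 skin pixels
  gt
}

test_that("confusion counts match their definitions", {
  gt <- mk_gt()
  cc <- confusion_counts(gt, gt)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 10L, FP = 0L, TN = 90L, FN = 0L))
  cc2 <- confusion_counts(1 - gt, gt)
  expect_equal(unlist(cc2[c("TP", "TN", "FP", "FN")]),
               c(TP = 0L, TN = 0L, FP = 90L, FN = 10L))
  cc3 <- confusion_counts(matrix(0, 10, 10), gt)
  expect_equal(cc3$FN, 10L); expect_equal(cc3$TN, 90L)
  expect_error(confusion_counts(matrix(0, 2, 2), gt), "share a shape")
  expect_error(confusion_counts(matrix(0.5, 10, 10), gt), "binary")
})

test_that("sensitivity and specificity are the printed ratios with NA guards", {
  ss <- sensitivity_specificity(list(TP = 8, FN = 2, TN = 90, FP = 10))
  expect_equal(unname(ss), c(0.8, 0.9))
  expect_equal(unname(sensitivity_specificity(list(TP = 5, FN = 0, TN = 7,
                                                   FP = 0))), c(1, 1))
  ss0 <- sensitivity_specificity(list(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(ss0[["sensitivity"]]))
  expect_equal(ss0[["specificity"]], 0.5)
})

test_that("ROC endpoints behave: perfect scores, chance scores, degenerate gt", {
  gt <- mk_gt()
  expect_equal(roc_curve(gt, gt)$auc, 1.0)
  expect_equal(roc_curve(matrix(0.7, 10, 10), gt)$auc, 0.5)
  expect_error(roc_curve(matrix(1, 4, 4), matrix(1, 4, 4)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise rank statistic with tie credit", {
  set.seed(51)
  for (i in 1:25) {
    gt <- matrix(0, 4, 5)
    gt[sample(20, sample(3:17, 1))] <- 1
    score <- matrix(sample(seq(0, 1, 0.1), 20, TRUE), 4, 5)  # many ties
    expect_equal(roc_curve(score, gt)$auc, mann_whitney_auc(score, gt),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone rescaling and flips with labels", {
  set.seed(52)
  gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  gt[1] <- 1; gt[2] <- 0
  score <- matrix(runif(64), 8, 8)
  a <- roc_curve(score, gt)$auc
  expect_equal(roc_curve(score^3, gt)$auc, a)
  expect_equal(roc_curve(plogis(5 * score), gt)$auc, a)
  expect_equal(roc_curve(score, 1 - gt)$auc, 1 - a, tolerance = 1e-12)
})

test_that("curves are anchored and monotone along the sweep", {
  set.seed(53)
  gt <- matrix(rbinom(100, 1, 0.2), 10, 10); gt[1] <- 1; gt[2] <- 0
  r <- roc_curve(matrix(runif(100), 10, 10), gt)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  r2 <- roc_curve(matrix(runif(100), 10, 10), gt, n_thresholds = 11)
  expect_lte(length(r2$thresholds), 11L)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  gt <- matrix(rbinom(200, 1, 0.4), 10, 20); gt[1] <- 1; gt[2] <- 0
  score <- matrix(runif(200), 10, 20) + 0.5 * gt
  ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(gt), as.numeric(score),
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_curve(score, gt)$auc, ref, tolerance = 1e-10)
})

test_that("batch evaluation yields one labelled row per pair", {
  gt <- mk_gt()
  tab <- evaluate_batch(list(gt, gt * 0.6), list(gt, gt),
                        labels = c("perfect", "soft"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$auc, c(1, 1))
  expect_equal(tab$sensitivity, c(1, 1))
  expect_equal(tab$label, c("perfect", "soft"))
  # duplicated pairs give identical rows
  tab2 <- evaluate_batch(list(gt, gt), list(gt, gt))
  expect_equal(tab2$auc[1], tab2$auc[2])
})
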