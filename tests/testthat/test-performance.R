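test_that("confusion counts with malignant as the positive class", {
  conf <- confusion_counts(rep(c("malignant", "benign"), c(5, 3)),
                           rep(c("malignant", "benign"), c(5, 3)))
  expect_equal(unclass(conf)[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 3L), ignore_attr = TRUE)
  allben <- confusion_counts(rep(c("malignant", "benign"), c(5, 3)),
                             rep("benign", 8))
  expect_equal(allben$tp + allben$fp, 0)
  expect_error(confusion_counts("malignant", c("benign", "benign")), "mismatch")
  expect_error(confusion_counts("tumour", "benign"), "benign")
})

test_that("metrics reproduce the combined-model headline proportions", {
  m <- diag_metrics(c(tp = 111, fp = 16, fn = 5, tn = 96))
  expect_equal(unname(m$percent["sensitivity"]), 95.7)
  expect_equal(unname(m$percent["specificity"]), 85.7)
  expect_equal(m$sensitivity, 111 / 116)
  expect_equal(m$specificity, 96 / 112)
  expect_equal(m$accuracy, 207 / 228)

  ct <- diag_metrics(c(tp = 108, fp = 51, fn = 8, tn = 62))
  expect_equal(unname(ct$percent["sensitivity"]), 93.1)

  perfect <- diag_metrics(c(tp = 4, fp = 0, fn = 0, tn = 6))
  expect_equal(perfect$accuracy, 1)
  expect_error(diag_metrics(c(tp = 0, fp = 2, fn = 0, tn = 2)), "sensitivity")
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(5)
  for (i in 1:20) {
    counts <- rpois(4, 20) + 1
    m <- diag_metrics(setNames(as.list(counts), c("tp", "fp", "fn", "tn")))
    prev <- (counts[1] + counts[3]) / sum(counts)
    expect_equal(m$accuracy, prev * m$sensitivity + (1 - prev) * m$specificity,
                 tolerance = 1e-12)
  }
})

test_that("binary AUC reproduces the validation-cohort values", {
  # validation CEUS: 52/61 sensitivity, 29/39 specificity
  expect_equal(round(binary_auc(c(tp = 52, fp = 10, fn = 9, tn = 29)), 3), 0.798)
  # validation combined model: 58/61 and 31/39
  expect_equal(round(binary_auc(c(tp = 58, fp = 8, fn = 3, tn = 31)), 3), 0.873)
  expect_equal(binary_auc(c(tp = 10, fp = 0, fn = 0, tn = 10)), 1)
  # chance classifier: sensitivity = 1 - specificity
  expect_equal(binary_auc(c(tp = 7, fp = 7, fn = 3, tn = 3)), 0.5)
})

test_that("ordinal AUC matches exhaustive pairwise enumeration to 1e-12", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(0:5, n, replace = TRUE)
    truth <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(ordinal_auc(scores, truth), auc_by_enumeration(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("ordinal AUC of the discovery C-TIRADS categories is 0.808", {
  scores <- category_rank(rep(c("4a", "4b", "4c", "4a", "4b", "4c"),
                              c(62, 47, 4, 7, 67, 41)))
  truth <- rep(c("benign", "malignant"), c(113, 115))
  expect_equal(round(ordinal_auc(scores, truth), 3), 0.808)
  expect_equal(ordinal_auc(scores, truth), auc_by_enumeration(scores, truth),
               tolerance = 1e-12)
})

test_that("ordinal AUC: ties give 0.5, separation gives 1, dichotomous equals binary", {
  truth <- rep(c("benign", "malignant"), each = 6)
  expect_equal(ordinal_auc(rep(2, 12), truth), 0.5)
  expect_equal(ordinal_auc(rep(c(0, 1), each = 6), truth), 1)
  expect_error(ordinal_auc(1:5, rep("benign", 5)), "both classes")
  set.seed(22)
  for (i in 1:10) {
    calls <- sample(c("benign", "malignant"), 40, replace = TRUE)
    tr <- sample(c("benign", "malignant"), 40, replace = TRUE)
    if (length(unique(tr)) < 2) next
    conf <- confusion_counts(tr, calls)
    if (conf$tp + conf$fn == 0 || conf$tn + conf$fp == 0) next
    expect_equal(ordinal_auc(as.integer(calls == "malignant"), tr),
                 binary_auc(conf), tolerance = 1e-12)
  }
})

test_that("the DeLong interval matches pROC and collapses on degenerate variance", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- c(rnorm(30), rnorm(25, 1))
  truth <- rep(c("benign", "malignant"), c(30, 25))
  res <- auc_ci(scores, truth)
  roc <- pROC::roc(truth, scores, levels = c("benign", "malignant"),
                   direction = "<", quiet = TRUE)
  ref <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  expect_equal(res$auc, ref[2], tolerance = 1e-10)
  expect_equal(res$ci, ref[c(1, 3)], tolerance = 1e-10)

  sep <- rep(c(0, 1), each = 5)
  tr <- rep(c("benign", "malignant"), each = 5)
  expect_warning(collapsed <- auc_ci(sep, tr), "degenerate")
  expect_equal(collapsed$ci, c(1, 1))
})

test_that("the interval is symmetric at AUC 0.5 and narrows with sample size", {
  truth <- rep(c("benign", "malignant"), each = 20)
  res <- auc_ci(rep(1:20, 2), truth)
  expect_equal(res$auc, 0.5)
  expect_equal(res$ci[2] - 0.5, 0.5 - res$ci[1], tolerance = 1e-10)
  set.seed(24)
  small <- auc_ci(c(rnorm(20), rnorm(20, 1)), rep(c("benign", "malignant"), each = 20))
  big <- auc_ci(c(rnorm(2000), rnorm(2000, 1)),
                rep(c("benign", "malignant"), each = 2000))
  expect_lt(diff(big$ci), diff(small$ci))
})

test_that("the paired DeLong test is antisymmetric and matches pROC", {
  set.seed(25)
  truth <- rep(c("benign", "malignant"), c(40, 35))
  a <- rnorm(75) + 1.2 * (truth == "malignant")
  b <- rnorm(75) + 0.4 * (truth == "malignant")
  res <- delong_test(a, b, truth)
  swapped <- delong_test(b, a, truth)
  expect_equal(res$delta, -swapped$delta)
  expect_equal(res$z, -swapped$z)
  expect_equal(res$p_value, swapped$p_value)

  same <- delong_test(a, a, truth)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(truth, a, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(truth, b, levels = c("benign", "malignant"),
                  direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$z, unname(ref$statistic), tolerance = 1e-10)
})

test_that("the paired test detects a large AUC difference at n = 200", {
  # predictors with true AUCs 0.9 and 0.6 on the same records
  mu_a <- qnorm(0.9) * sqrt(2)
  mu_b <- qnorm(0.6) * sqrt(2)
  truth <- rep(c("benign", "malignant"), each = 100)
  set.seed(27)
  rejections <- replicate(500, {
    a <- rnorm(200) + mu_a * (truth == "malignant")
    b <- rnorm(200) + mu_b * (truth == "malignant")
    delong_test(a, b, truth)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("youden_cutoff agrees with an exhaustive threshold scan", {
  scan_oracle <- function(scores, truth) {
    mal <- scores[truth == "malignant"]
    ben <- scores[truth == "benign"]
    cands <- sort(unique(scores))
    best <- -Inf
    best_t <- NA
    for (t in cands) {
      j <- mean(mal >= t) + mean(ben < t) - 1
      if (j > best) {
        best <- j
        best_t <- t
      }
    }
    list(threshold = best_t, j = best)
  }
  set.seed(26)
  for (i in 1:20) {
    scores <- sample(0:5, 30, replace = TRUE)
    truth <- sample(c("benign", "malignant"), 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    res <- youden_cutoff(scores, truth)
    ref <- scan_oracle(scores, truth)
    expect_equal(res$j, ref$j, tolerance = 1e-12)
    expect_equal(res$threshold, ref$threshold)
  }
  # perfectly separated ordinals: threshold between the classes, J = 1
  res <- youden_cutoff(rep(c(0, 3), each = 10), rep(c("benign", "malignant"), each = 10))
  expect_equal(res$threshold, 3)
  expect_equal(res$j, 1)
})

test_that("a CEUS-score-like mixture puts the Youden cutoff at 2", {
  # scores concentrated low among benign and high among malignant nodules
  scores <- c(rep(0:2, c(60, 25, 7)), rep(c(0, 1, 2, 3, 4), c(10, 15, 30, 35, 26)))
  truth <- rep(c("benign", "malignant"), c(92, 116))
  expect_equal(youden_cutoff(scores, truth)$threshold, 2)
})
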