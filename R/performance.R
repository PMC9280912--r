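# Diagnostic performance: confusion counts, sensitivity/specificity/
# accuracy, binary and ordinal AUC, DeLong variance/CI/comparison,
# Youden cutoff.

#' Confusion counts of a dichotomous call against pathology
#'
#' Malignant is the positive class: `tp` counts malignant nodules called
#' malignant, `tn` benign called benign, and so on. The four counts
#' partition the cohort.
#'
#' @param truth per-record pathology, `"benign"`/`"malignant"`.
#' @param calls per-record prediction in the same vocabulary.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c("malignant", "benign"), c("malignant", "malignant"))
#' @export
confusion_counts <- function(truth, calls) {
  truth <- as.character(truth)
  calls <- as.character(calls)
  if (length(truth) != length(calls)) stop("length mismatch", call. = FALSE)
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  ok <- c("benign", "malignant")
  if (!all(truth %in% ok) || !all(calls %in% ok)) {
    stop("truth and calls must be 'benign' or 'malignant'", call. = FALSE)
  }
  out <- list(tp = sum(truth == "malignant" & calls == "malignant"),
              fp = sum(truth == "benign" & calls == "malignant"),
              fn = sum(truth == "malignant" & calls == "benign"),
              tn = sum(truth == "benign" & calls == "benign"))
  class(out) <- "confusion_counts"
  out
}

as_confusion <- function(conf) {
  if (inherits(conf, "confusion_counts")) return(conf)
  need <- c("tp", "fp", "fn", "tn")
  if (is.null(names(conf)) || !all(need %in% names(conf))) {
    stop("confusion counts need named elements tp, fp, fn, tn", call. = FALSE)
  }
  out <- as.list(conf[need])
  class(out) <- "confusion_counts"
  out
}

#' Sensitivity, specificity and accuracy
#'
#' The three headline proportions of a dichotomous diagnostic call:
#' sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/total. Percentages rounded to 1 decimal are exposed alongside
#' for report formatting.
#'
#' @param conf a `confusion_counts` object or named vector/list with
#'   `tp`, `fp`, `fn`, `tn`.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `n`, and
#'   `percent` (named vector at 1 d.p.).
#' @examples
#' diag_metrics(c(tp = 111, fp = 16, fn = 5, tn = 96))
#' @export
diag_metrics <- function(conf) {
  conf <- as_confusion(conf)
  if (conf$tp + conf$fn == 0) stop("undefined metric: sensitivity (no malignant cases)", call. = FALSE)
  if (conf$tn + conf$fp == 0) stop("undefined metric: specificity (no benign cases)", call. = FALSE)
  n <- conf$tp + conf$fp + conf$fn + conf$tn
  sens <- conf$tp / (conf$tp + conf$fn)
  spec <- conf$tn / (conf$tn + conf$fp)
  acc <- (conf$tp + conf$tn) / n
  list(sensitivity = sens, specificity = spec, accuracy = acc, n = n,
       percent = round(100 * c(sensitivity = sens, specificity = spec,
                               accuracy = acc), 1))
}

#' AUC of a single-threshold (dichotomous) predictor
#'
#' The ROC curve of a binary call has a single interior point, so the
#' trapezoidal area reduces to (sensitivity + specificity) / 2.
#'
#' @inheritParams diag_metrics
#' @return numeric AUC in 0..1.
#' @examples
#' binary_auc(c(tp = 52, fp = 10, fn = 9, tn = 29))
#' @export
binary_auc <- function(conf) {
  m <- diag_metrics(conf)
  (m$sensitivity + m$specificity) / 2
}

split_scores <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) stop("length mismatch", call. = FALSE)
  mal <- scores[truth == "malignant"]
  ben <- scores[truth == "benign"]
  if (length(mal) == 0 || length(ben) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  list(mal = as.numeric(mal), ben = as.numeric(ben))
}

#' AUC of an ordinal score (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen malignant nodule scores higher
#' than a randomly chosen benign one, with ties counted one half —
#' computed by the rank formula over all benign-malignant pairs.
#'
#' @param scores numeric or ordinal score per record (use
#'   [category_rank()] to score categories).
#' @param truth per-record pathology.
#' @return numeric AUC in 0..1.
#' @examples
#' ordinal_auc(c(1, 2, 3, 1), c("benign", "malignant", "malignant", "benign"))
#' @export
ordinal_auc <- function(scores, truth) {
  s <- split_scores(scores, truth)
  m <- length(s$mal)
  n <- length(s$ben)
  r <- rank(c(s$mal, s$ben))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: for each malignant score the mean of
# psi(y, z) over benign scores (V10), and vice versa (V01), with
# psi = 1, 1/2, 0 for y > z, y == z, y < z.
delong_components <- function(mal, ben) {
  psi <- outer(mal, ben, function(y, z) (y > z) + 0.5 * (y == z))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong confidence interval for an ordinal AUC
#'
#' Asymptotic normal interval with the DeLong structural-components
#' variance, clipped to 0..1. A degenerate variance (e.g. perfectly
#' separated classes) collapses the interval to the point estimate with a
#' warning.
#'
#' @inheritParams ordinal_auc
#' @param conf_level confidence level, default 0.95.
#' @return list with `auc`, `ci` (length-2 vector), `se`.
#' @export
auc_ci <- function(scores, truth, conf_level = 0.95) {
  s <- split_scores(scores, truth)
  if (length(s$mal) < 2 || length(s$ben) < 2) {
    stop("need at least 2 records per class", call. = FALSE)
  }
  comp <- delong_components(s$mal, s$ben)
  v <- stats::var(comp$v10) / length(s$mal) + stats::var(comp$v01) / length(s$ben)
  if (v <= 0) {
    warning("degenerate AUC variance; interval collapsed to the estimate")
    return(list(auc = comp$auc, ci = c(comp$auc, comp$auc), se = 0))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- comp$auc + c(-1, 1) * z * sqrt(v)
  list(auc = comp$auc, ci = pmin(pmax(ci, 0), 1), se = sqrt(v))
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Both predictors are scored on the same records, so their AUCs are
#' correlated; the DeLong z-test accounts for this via the covariance of
#' the structural components. Two-sided p-value. Identical predictors
#' give delta 0 and p 1 by definition.
#'
#' @param scores_a,scores_b per-record scores of the two predictors.
#' @inheritParams ordinal_auc
#' @return list with `auc_a`, `auc_b`, `delta` (`auc_a - auc_b`), `z`,
#'   `p_value`.
#' @examples
#' truth <- rep(c("benign", "malignant"), each = 10)
#' delong_test(seq_len(20), rep(c(0, 1), each = 10), truth)
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  sa <- split_scores(scores_a, truth)
  sb <- split_scores(scores_b, truth)
  ca <- delong_components(sa$mal, sa$ben)
  cb <- delong_components(sb$mal, sb$ben)
  delta <- ca$auc - cb$auc
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / length(sa$mal) +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / length(sa$ben)
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z, p_value = p)
}

#' Youden-optimal cutoff of an ordinal score
#'
#' Scans every observed score value as a candidate threshold (a record is
#' called malignant when its score is greater than or equal to the
#' threshold) and returns the threshold maximising the Youden index
#' J = sensitivity + specificity - 1; ties are broken toward the lowest
#' threshold.
#'
#' @inheritParams ordinal_auc
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`.
#' @examples
#' youden_cutoff(c(0, 1, 2, 4, 3, 0), rep(c("benign", "malignant"), each = 3))
#' @export
youden_cutoff <- function(scores, truth) {
  s <- split_scores(scores, truth)
  cand <- sort(unique(c(s$mal, s$ben)))
  sens <- vapply(cand, function(t) mean(s$mal >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(s$ben < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}
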