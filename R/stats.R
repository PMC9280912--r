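# Model-building statistics: contingency tests, two-sample t, logistic
# regression, odds ratios and the OR -> integer-weight derivation.

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic, sum((O-E)^2/E) with expected counts from the
#' margins and no continuity correction (the convention that reproduces
#' the published feature-screening values), with the p-value from the
#' chi-square distribution on (r-1)(c-1) degrees of freedom.
#'
#' @param table numeric matrix of nonnegative counts, at least 2x2; rows
#'   are feature levels, columns outcome classes.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' arrival <- matrix(c(52, 12, 64, 80), nrow = 2, byrow = TRUE,
#'                   dimnames = list(c("later", "equal_or_earlier"),
#'                                   c("malignant", "benign")))
#' pearson_chi2(arrival)
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(is.na(table)) || any(table < 0)) {
    stop("table must contain nonnegative counts", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2 || sum(table) < 1) {
    stop("table must be at least 2x2 with a positive grand total", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Two-sample t-tests
#'
#' `two_sample_t()` compares two samples of measurements; the default is
#' the pooled-variance Student form, `welch = TRUE` gives the
#' Welch-Satterthwaite form. `t_test_summary()` is the same test computed
#' from summary statistics (mean, SD, n per group), for checking published
#' tables that report only summaries.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param welch logical; use the Welch form.
#' @return list with `t`, `df`, `p_value` (two-sided), `group_means`,
#'   `group_sds`.
#' @examples
#' t_test_summary(41.6, 11.1, 116, 46.9, 12.7, 112)
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample must have at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    stop("t statistic undefined: both samples constant and equal", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value),
       group_means = c(mean(x), mean(y)),
       group_sds = c(stats::sd(x), stats::sd(y)))
}

#' @rdname two_sample_t
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    stop("t statistic undefined: both samples constant and equal", call. = FALSE)
  }
  if (!welch) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se1 <- sd1^2 / n1
    se2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       group_means = c(mean1, mean2), group_sds = c(sd1, sd2))
}

#' Multivariable logistic regression
#'
#' Maximum-likelihood logistic fit of malignancy on a panel of binary
#' indicators, by iteratively reweighted least squares (convergence when
#' the deviance step falls below 1e-8, at most 50 iterations; intercept
#' always included). Standard errors come from the inverse observed
#' information. Perfect separation is detected from boundary fitted
#' probabilities and flagged as non-converged rather than silently
#' returning divergent estimates.
#'
#' @param predictors data.frame or matrix of 0/1 (or logical) indicator
#'   columns, one row per record.
#' @param outcome per-record outcome: `"benign"`/`"malignant"`, a factor,
#'   or 0/1 (1 = malignant).
#' @return list with `coefficients` (log-odds, including `(Intercept)`),
#'   `standard_errors`, `odds_ratios` (`exp(coefficients)`), `converged`,
#'   `iterations`, and `note` (non-empty when separation was detected).
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rbinom(200, 1, 0.5), b = rbinom(200, 1, 0.5))
#' y <- rbinom(200, 1, stats::plogis(-1 + 1.5 * x$a + 0.5 * x$b))
#' fit_logistic(x, y)$odds_ratios
#' @export
fit_logistic <- function(predictors, outcome) {
  x <- as.data.frame(predictors)
  if (ncol(x) < 1) stop("need at least one predictor", call. = FALSE)
  x[] <- lapply(x, function(col) as.numeric(as.logical(as.numeric(col))))
  if (is.character(outcome) || is.factor(outcome)) {
    y <- as.integer(as.character(outcome) == "malignant")
  } else {
    y <- as.integer(outcome)
  }
  if (length(y) != nrow(x)) stop("outcome length mismatch", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  constant <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(constant)) {
    stop("constant predictor(s): ", paste(names(x)[constant], collapse = ", "),
         call. = FALSE)
  }
  dat <- cbind(x, .y = y)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  )
  coefs <- stats::coef(fit)
  if (any(is.na(coefs))) {
    stop("singular information matrix: predictors are linearly dependent",
         call. = FALSE)
  }
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  se <- sqrt(diag(stats::vcov(fit)))
  list(coefficients = coefs,
       standard_errors = se,
       odds_ratios = exp(coefs),
       converged = fit$converged && !separated,
       iterations = fit$iter,
       note = if (separated) "perfect or quasi-perfect separation detected" else "")
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `ad/bc` with a 95% Woolf (log-scale normal)
#' confidence interval. With a zero cell the estimate is undefined; set
#' `haldane = TRUE` to add 0.5 to every cell (Haldane-Anscombe
#' correction).
#'
#' @param table 2x2 count matrix; rows = exposure (risk level first),
#'   columns = outcome (malignant first).
#' @param haldane logical; apply the +0.5 correction.
#' @return list with `or` and `ci95` (length-2 vector).
#' @examples
#' odds_ratio_2x2(matrix(c(52, 12, 64, 80), nrow = 2, byrow = TRUE))
#' @export
odds_ratio_2x2 <- function(table, haldane = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    stop("need a 2x2 table of nonnegative counts", call. = FALSE)
  }
  if (any(table == 0) && !haldane) {
    stop("zero cell: odds ratio undefined; consider haldane = TRUE (+0.5 correction)",
         call. = FALSE)
  }
  if (haldane) table <- table + 0.5
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  se <- sqrt(sum(1 / table))
  list(or = or, ci95 = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se))
}

#' Derive integer score weights from odds ratios
#'
#' The published counting rule: the risk feature with the strictly largest
#' odds ratio is weighted 2, every other feature 1. Features tied for the
#' largest odds ratio all receive 2 and the result is flagged. Every
#' feature must be a risk factor (OR > 1).
#'
#' @param or_by_feature named numeric vector of odds ratios.
#' @return named integer weights in input order, with attribute `tie`
#'   (logical).
#' @examples
#' derive_weights(c(hypo_enhancement = 39, later_arrival = 24,
#'                  centripetal = 12, heterogeneous = 6))
#' @export
derive_weights <- function(or_by_feature) {
  if (is.null(names(or_by_feature)) || any(names(or_by_feature) == "")) {
    stop("odds ratios must be named by feature", call. = FALSE)
  }
  if (any(is.na(or_by_feature)) || any(or_by_feature <= 1)) {
    stop("all odds ratios must exceed 1 (risk direction)", call. = FALSE)
  }
  top <- or_by_feature == max(or_by_feature)
  w <- ifelse(top, 2L, 1L)
  names(w) <- names(or_by_feature)
  attr(w, "tie") <- sum(top) > 1
  w
}

# Per-class level counts for one CEUS feature, risk level(s) first.
feature_table <- function(cohort, feature) {
  levels <- switch(feature,
    enhancement_degree = c("hypo", "iso", "hyper"),
    arrival            = c("later", "equal_or_earlier"),
    homogeneity        = c("heterogeneous", "homogeneous"),
    pattern            = c("centripetal", "diffuse"),
    washout            = c("earlier", "later_or_equal"),
    peripheral_ring    = c("yes", "no"),
    stop("unknown CEUS feature: ", feature, call. = FALSE))
  x <- cohort[[feature]]
  if (feature == "peripheral_ring") x <- ifelse(x, "yes", "no")
  counts <- vapply(c("malignant", "benign"), function(cls) {
    vapply(levels, function(lv) sum(x == lv & cohort$pathology == cls, na.rm = TRUE),
           numeric(1))
  }, numeric(length(levels)))
  matrix(counts, nrow = length(levels),
         dimnames = list(levels, c("malignant", "benign")))
}

#' Univariate chi-square screen of CEUS features
#'
#' One Pearson chi-square test per CEUS feature against pathology, over
#' the enhancing nodules of a labelled cohort: enhancement degree as a
#' 3-level factor (hypo / iso / hyper), the other five features as
#' 2-level. A feature is selected when p < `alpha`.
#'
#' @param cohort labelled `ceus_cohort` (pathology required; nodules with
#'   absent enhancement are dropped before testing).
#' @param alpha significance level, default 0.05.
#' @return data.frame with one row per feature: `feature`, `statistic`,
#'   `df`, `p_value`, `selected`.
#' @examples
#' univariate_screen(table2_cohort())
#' @export
univariate_screen <- function(cohort, alpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  if (!"pathology" %in% names(cohort) || any(is.na(cohort$pathology))) {
    stop("cohort must carry pathology labels for every record", call. = FALSE)
  }
  enh <- cohort[!is.na(cohort$enhancement_degree) &
                cohort$enhancement_degree != "absent", , drop = FALSE]
  feats <- ceus_feature_names()
  rows <- lapply(feats, function(f) {
    res <- pearson_chi2(feature_table(enh, f))
    data.frame(feature = f, statistic = res$statistic, df = res$df,
               p_value = res$p_value, selected = res$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
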