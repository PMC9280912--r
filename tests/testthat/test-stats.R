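# Independent brute-force oracle for the Pearson statistic.
chi2_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

arrival_table <- matrix(c(52, 12, 64, 80), nrow = 2, byrow = TRUE)

test_that("pearson_chi2 reproduces the published arrival-time and washout statistics", {
  res <- pearson_chi2(arrival_table)
  expect_equal(round(res$statistic, 3), 24.333)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  washout <- matrix(c(20, 8, 96, 84), nrow = 2, byrow = TRUE)
  expect_equal(round(pearson_chi2(washout)$statistic, 3), 3.216)
  expect_gt(pearson_chi2(washout)$p_value, 0.05)

  degree <- matrix(c(73, 18, 26, 45, 17, 29), nrow = 3, byrow = TRUE)
  res3 <- pearson_chi2(degree)
  expect_equal(round(res3$statistic, 2), 39.21)
  expect_equal(res3$df, 2)
})

test_that("pearson_chi2 agrees with the direct sum((O-E)^2/E) oracle", {
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 20) + 1, nrow = sample(2:3, 1))
    expect_equal(pearson_chi2(tab)$statistic, chi2_oracle(tab), tolerance = 1e-12)
  }
  # the ring table recomputes to ~37.40 by both routes
  ring <- matrix(c(1, 28, 115, 64), nrow = 2, byrow = TRUE)
  expect_equal(pearson_chi2(ring)$statistic, chi2_oracle(ring), tolerance = 1e-12)
  expect_equal(round(pearson_chi2(ring)$statistic, 2), 37.40)
})

test_that("pearson_chi2 invariances: permutation, scaling, proportional rows", {
  set.seed(12)
  tab <- matrix(rpois(4, 30) + 1, nrow = 2)
  base <- pearson_chi2(tab)$statistic
  expect_equal(pearson_chi2(tab[2:1, ])$statistic, base)
  expect_equal(pearson_chi2(tab[, 2:1])$statistic, base)
  expect_equal(pearson_chi2(3 * tab)$statistic, 3 * base, tolerance = 1e-12)
  prop <- rbind(c(10, 20), c(30, 60))
  expect_equal(pearson_chi2(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "degenerate")
})

test_that("the summary-statistic t-test reproduces the published age comparison", {
  age <- t_test_summary(41.6, 11.1, 116, 46.9, 12.7, 112)
  expect_equal(round(age$p_value, 3), 0.001)
  expect_lt(age$t, 0)
  expect_equal(age$df, 226)
  # Welch and pooled agree when variances and sizes are equal
  a <- t_test_summary(1, 2, 30, 1.5, 2, 30)
  b <- t_test_summary(1, 2, 30, 1.5, 2, 30, welch = TRUE)
  expect_equal(a$t, b$t)
  expect_equal(a$df, b$df)
})

test_that("the sample t-test matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(2, 4, 4, 7, 9, 11)
  res <- two_sample_t(x, y)
  byhand <- t_test_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_equal(res$t, byhand$t, tolerance = 1e-12)
  expect_equal(res$p_value, byhand$p_value, tolerance = 1e-12)
  resw <- two_sample_t(x, y, welch = TRUE)
  byhandw <- t_test_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                            welch = TRUE)
  expect_equal(resw$t, byhandw$t, tolerance = 1e-12)
  expect_equal(two_sample_t(x, x)$t, 0)
  expect_equal(two_sample_t(x, x)$p_value, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "undefined")
})

test_that("fit_logistic on one binary predictor equals the closed-form 2x2 log-OR", {
  # predictor distributed like the arrival-time table
  x <- rep(c(1, 0, 1, 0), c(52, 64, 12, 80))
  y <- rep(c("malignant", "benign"), c(116, 92))
  fit <- fit_logistic(data.frame(later = x), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["later"]), log(52 * 80 / (64 * 12)),
               tolerance = 1e-6)
  expect_equal(unname(fit$odds_ratios["later"]), 5.4167, tolerance = 1e-3)
})

test_that("fit_logistic recovers known two-predictor effects and flags pathologies", {
  set.seed(31)
  n <- 2000
  x <- data.frame(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.5))
  true_beta <- c(log(39), log(24))
  eta <- -2 + true_beta[1] * x$a + true_beta[2] * x$b
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["a"] - true_beta[1]), 3 * fit$standard_errors["a"])
  expect_lt(abs(fit$coefficients["b"] - true_beta[2]), 3 * fit$standard_errors["b"])

  expect_error(fit_logistic(data.frame(a = rep(1, 10)), rep(0:1, 5)), "constant")
  expect_error(fit_logistic(data.frame(a = rep(0:1, 5)), rep(1, 10)), "both classes")
  # perfect separation is flagged, not silently returned
  sep <- fit_logistic(data.frame(a = rep(0:1, each = 20)),
                      rep(c("benign", "malignant"), each = 20))
  expect_false(sep$converged)
  expect_match(sep$note, "separation")
})

test_that("a balanced outcome-independent predictor has coefficient 0", {
  x <- rep(c(0, 1, 0, 1), each = 25)
  y <- rep(c("benign", "benign", "malignant", "malignant"), each = 25)
  fit <- fit_logistic(data.frame(a = x), y)
  expect_equal(unname(fit$coefficients["a"]), 0, tolerance = 1e-8)
})

test_that("odds_ratio_2x2: closed form, symmetry, zero-cell handling", {
  res <- odds_ratio_2x2(arrival_table)
  expect_equal(round(res$or, 3), 5.417)
  expect_true(res$ci95[1] > 1 && res$ci95[1] < res$or && res$ci95[2] > res$or)
  expect_equal(odds_ratio_2x2(matrix(1, 2, 2))$or, 1)
  flipped <- odds_ratio_2x2(arrival_table[2:1, ])
  expect_equal(flipped$or, 1 / res$or, tolerance = 1e-12)
  withzero <- matrix(c(5, 0, 3, 7), nrow = 2)
  expect_error(odds_ratio_2x2(withzero), "haldane")
  expect_gt(odds_ratio_2x2(withzero, haldane = TRUE)$or, 0)
})

test_that("derive_weights gives the dominant feature 2 and the rest 1", {
  w <- derive_weights(c(hypo_enhancement = 39, later_arrival = 24,
                        centripetal = 12, heterogeneous = 6))
  expect_equal(as.integer(w), c(2L, 1L, 1L, 1L))
  expect_equal(names(w), c("hypo_enhancement", "later_arrival",
                           "centripetal", "heterogeneous"))
  expect_false(attr(w, "tie"))

  tied <- derive_weights(c(a = 5, b = 5, c = 5))
  expect_equal(as.integer(tied), c(2L, 2L, 2L))
  expect_true(attr(tied, "tie"))

  expect_equal(as.integer(derive_weights(c(solo = 3))), 2L)
  expect_error(derive_weights(c(a = 2, b = 0.8)), "exceed 1")
})

test_that("univariate screening of the reconstructed feature table selects all but washout", {
  screen <- univariate_screen(table2_cohort())
  expect_equal(nrow(screen), 6)
  arr <- screen[screen$feature == "arrival", ]
  expect_equal(round(arr$statistic, 3), 24.333)
  expect_true(arr$selected)
  was <- screen[screen$feature == "washout", ]
  expect_equal(round(was$statistic, 3), 3.216)
  expect_false(was$selected)
  expect_equal(screen$selected, screen$feature != "washout")

  single <- table2_cohort()
  single$pathology <- "malignant"
  expect_error(univariate_screen(single), "degenerate")
})
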