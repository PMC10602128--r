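test_that("confusion rates handle identity, order shuffles and degenerate input", {
  y <- c(1, 1, 0, 0, 1, 0)
  r <- confusion_rates(y, y)
  expect_equal(r$tpr, 1); expect_equal(r$tnr, 1)
  expect_equal(r$pos_mismatch_pct, 0); expect_equal(r$neg_mismatch_pct, 0)

  ref <- c(1, 1, 1, 0, 0, 0, 0, 1)
  cmp <- c(1, 0, 1, 0, 1, 0, 0, 0)
  a <- confusion_rates(ref, cmp)
  perm <- withr::with_seed(1, sample(8))
  b <- confusion_rates(ref[perm], cmp[perm])
  expect_identical(a[c("tp", "tn", "fp", "fn")], b[c("tp", "tn", "fp", "fn")])

  expect_warning(r0 <- confusion_rates(c(0, 0), c(0, 1)), "no reference positives")
  expect_true(is.na(r0$tpr))
  expect_error(confusion_rates(c(1, NA), c(1, 0)),
               class = "thetapet_validation_error")
  expect_error(confusion_rates(c(1, 0, 1), c(1, 0)),
               class = "thetapet_integrity_error")
})

test_that("published confusion counts reproduce the printed mismatch rates", {
  # model vs visual, discovery cohort: TP=236/245+, TN=1040/1045-
  r <- confusion_rates_from_counts(tp = 236, tn = 1040, n_pos = 245, n_neg = 1045)
  expect_equal(r$pos_mismatch_pct, 3.67)
  expect_equal(r$neg_mismatch_pct, 0.48)
  # MTL meta-ROI vs visual: TP=191 of 245
  r2 <- confusion_rates_from_counts(tp = 191, tn = 993, n_pos = 245, n_neg = 1045)
  expect_equal(r2$pos_mismatch_pct, 22.04)
})

test_that("midrank AUC agrees with hand-worked values and the pair-count oracle", {
  # 6-point hand-worked set: one discordant pair (0.35+ vs 0.4-) of 9
  # positive/negative pairs -> AUC = 8/9, confirmed by the pair-count oracle
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.8, 0.7)
  labels <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(labels, scores), 8 / 9)
  expect_equal(brute_auc(labels, scores), 8 / 9)
  # perfect separation and anti-correlation
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_lt(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0.5)
  expect_warning(auc_c <- roc_auc(c(0, 1), c(0.5, 0.5)), "constant")
  expect_equal(auc_c, 0.5)
  # oracle equivalence with ties, up to n = 200
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), 2)   # coarse grid forces ties
      expect_equal(roc_auc(labels, scores), brute_auc(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("midrank AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    labels <- rbinom(150, 1, 0.3)
    scores <- rnorm(150) + labels
    expect_equal(roc_auc(labels, scores),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("classification metrics cover MCC and degenerate separations", {
  m <- classification_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                              c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$roc_auc, 1.0)
  expect_equal(m$mcc, 1.0)
  expect_equal(m$f1, 1.0)
  m2 <- classification_metrics(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(m2$mcc, -1.0)
  expect_equal(m2$balanced_accuracy, 0)
})

test_that("spearman/OLS association reports behave on exact and null cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- spearman_ols(x, 2 * x + 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$ols_slope, 2)
  expect_equal(r$ols_intercept, 1)
  expect_equal(r$n_pairs, 5L)
  # monotone invariance: rho = -1 for y = -x^3, slope is not -1
  r2 <- spearman_ols(x, -x^3)
  expect_equal(r2$spearman_rho, -1)
  expect_false(isTRUE(all.equal(r2$ols_slope, -1)))
  # independence: small rho at large n
  withr::with_seed(17, {
    xx <- rnorm(2000); yy <- rnorm(2000)
    expect_lt(abs(spearman_ols(xx, yy)$spearman_rho), 0.08)
  })
  # missing values use complete pairs only
  r3 <- spearman_ols(c(x, NA), c(2 * x + 1, 5))
  expect_equal(r3$n_pairs, 5L)
  expect_error(spearman_ols(c(1, 2), c(1, 2)),
               class = "thetapet_validation_error")
  expect_warning(spearman_ols(rep(1, 5), x), "constant")
})

test_that("Cohen's d uses the pooled SD and Bonferroni caps at one", {
  r <- cohens_d_ttest(c(2, 4), c(0, 2))
  expect_equal(r$cohens_d, sqrt(2), tolerance = 1e-12)
  r0 <- cohens_d_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$cohens_d, 0)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # capping
  ra <- cohens_d_ttest(c(1, 2, 3, 5), c(1.5, 2.5, 3, 4), n_comparisons = 4)
  expect_lte(ra$p_adjusted, 1)
  expect_equal(ra$p_adjusted, min(1, ra$p_value * 4))
  expect_gte(ra$p_adjusted, ra$p_value)   # adjustment is monotone
  expect_warning(cohens_d_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
  # pooled t equals stats::t.test with var.equal
  a <- c(2.2, 3.1, 2.8, 3.9); b <- c(1.2, 2.0, 1.1)
  expect_equal(cohens_d_ttest(a, b)$t_statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic))
  expect_equal(cohens_d_ttest(a, b, welch = TRUE)$t_statistic,
               unname(t.test(a, b)$statistic))
})

test_that("ICC(2,1) matches hand computation and its boundary behaviour", {
  M <- cbind(run1 = c(1, 2, 3, 4), run2 = c(1, 2, 3, 4))
  expect_equal(icc_across_runs(M), 1.0)
  # constant offset between runs: MSR = 10/3, MSC = 2, MSE = 0
  # ICC = (10/3) / (10/3 + 2*(2)/4) = 10/13
  M2 <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(icc_across_runs(M2), 10 / 13, tolerance = 1e-12)
  # independent runs: near zero at large n
  withr::with_seed(19, {
    M3 <- cbind(rnorm(500), rnorm(500), rnorm(500))
    expect_lt(abs(icc_across_runs(M3)), 0.15)
  })
  expect_warning(icc_null <- icc_across_runs(matrix(1, 4, 2)), "constant")
  expect_true(is.na(icc_null))
  expect_error(icc_across_runs(matrix(1:4, 2, 2)),
               class = "thetapet_validation_error")
})
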