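#' Confusion counts and mismatch rates against a reference rating
#'
#' Builds the 2x2 table treating `reference` (the visual rating in the
#' intended use) as truth, and derives sensitivity (TPR), specificity (TNR)
#' and the mismatch rates 1-TPR and 1-TNR. Percentage rates are reported
#' rounded (round-half-even) to 2 decimals.
#'
#' @param reference,comparator 0/1 vectors of equal length, no missing values.
#' @return Object of class `metrics_report` with `tp`, `tn`, `fp`, `fn`,
#'   `tpr`, `tnr`, `pos_mismatch`, `neg_mismatch` and the rounded
#'   `pos_mismatch_pct`, `neg_mismatch_pct`.
#' @export
confusion_rates <- function(reference, comparator) {
  if (length(reference) != length(comparator)) {
    stop_thetapet("thetapet_integrity_error", "label vectors differ in length")
  }
  if (anyNA(reference) || anyNA(comparator)) {
    stop_thetapet("thetapet_validation_error", "labels must not be missing")
  }
  if (!is_binary01(as.numeric(reference)) || !is_binary01(as.numeric(comparator))) {
    stop_thetapet("thetapet_validation_error", "labels must be 0/1")
  }
  tp <- sum(reference == 1 & comparator == 1)
  tn <- sum(reference == 0 & comparator == 0)
  fp <- sum(reference == 0 & comparator == 1)
  fn <- sum(reference == 1 & comparator == 0)
  tpr <- if (tp + fn == 0L) {
    warning("no reference positives; TPR undefined")
    NA_real_
  } else tp / (tp + fn)
  tnr <- if (tn + fp == 0L) {
    warning("no reference negatives; TNR undefined")
    NA_real_
  } else tn / (tn + fp)
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn, tpr = tpr, tnr = tnr,
         pos_mismatch = 1 - tpr, neg_mismatch = 1 - tnr,
         pos_mismatch_pct = round(100 * (1 - tpr), 2),
         neg_mismatch_pct = round(100 * (1 - tnr), 2),
         balanced_accuracy = (tpr + tnr) / 2),
    class = "metrics_report"
  )
}

#' Confusion report from published counts
#'
#' Convenience wrapper that reconstructs label vectors from a printed
#' confusion summary (true positives, true negatives, reference totals) and
#' delegates to [confusion_rates()].
#'
#' @param tp,tn True positive / true negative counts.
#' @param n_pos,n_neg Reference positive / negative totals.
#' @return A `metrics_report`.
#' @export
confusion_rates_from_counts <- function(tp, tn, n_pos, n_neg) {
  stopifnot(tp <= n_pos, tn <= n_neg)
  reference <- c(rep(1L, n_pos), rep(0L, n_neg))
  comparator <- c(rep(1L, tp), rep(0L, n_pos - tp),
                  rep(0L, tn), rep(1L, n_neg - tn))
  confusion_rates(reference, comparator)
}

#' Midrank (trapezoidal) ROC AUC
#'
#' Rank-based AUC equal to the normalized Mann-Whitney statistic; ties are
#' handled by midranks, which matches the trapezoidal area over all
#' thresholds.
#'
#' @param reference 0/1 labels.
#' @param probabilities Scores aligned with `reference`.
#' @return AUC in [0, 1]; 0.5 with a warning for constant scores.
#' @export
roc_auc <- function(reference, probabilities) {
  n1 <- sum(reference == 1)
  n0 <- sum(reference == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class reference; AUC undefined")
    return(NA_real_)
  }
  if (length(unique(probabilities)) == 1L) {
    warning("constant probabilities; AUC = 0.5")
    return(0.5)
  }
  r <- rank(probabilities)
  (sum(r[reference == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full classification metrics report
#'
#' Extends [confusion_rates()] with balanced accuracy, Matthews correlation
#' coefficient, precision, recall, F1 and midrank ROC AUC.
#'
#' @param reference,predicted 0/1 vectors.
#' @param probabilities Optional scores for the AUC (defaults to `predicted`).
#' @return A `metrics_report`.
#' @export
classification_metrics <- function(reference, predicted,
                                   probabilities = predicted) {
  rep0 <- confusion_rates(reference, predicted)
  tp <- rep0$tp; tn <- rep0$tn; fp <- rep0$fp; fn <- rep0$fn
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  rep0$mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  rep0$precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  rep0$recall <- rep0$tpr
  rep0$f1 <- if (is.na(rep0$precision) || is.na(rep0$recall) ||
                 rep0$precision + rep0$recall == 0) NA_real_
             else 2 * rep0$precision * rep0$recall / (rep0$precision + rep0$recall)
  rep0$roc_auc <- roc_auc(reference, probabilities)
  rep0
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP %d / FN %d / TN %d / FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  TPR %.4f  TNR %.4f  (mismatch %.2f%% / %.2f%%)\n",
              x$tpr, x$tnr, x$pos_mismatch_pct, x$neg_mismatch_pct))
  if (!is.null(x$roc_auc)) {
    cat(sprintf("  bal.acc %.4f  MCC %.4f  F1 %.4f  AUC %.4f\n",
                x$balanced_accuracy, x$mcc, x$f1, x$roc_auc))
  }
  invisible(x)
}

#' Spearman correlation and OLS association
#'
#' Midrank Spearman rho together with an ordinary least squares fit of `y` on
#' `x`, on complete pairs only.
#'
#' @param x Score (e.g. THETA or a meta-ROI SUVR).
#' @param y Clinical measure (e.g. MMSE, CDR-SB).
#' @return Object of class `association_report`: `spearman_rho`, `ols_slope`,
#'   `ols_intercept`, `n_pairs`.
#' @export
spearman_ols <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_thetapet("thetapet_validation_error", "need >= 3 complete pairs")
  }
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    NA_real_
  } else stats::cor(x, y, method = "spearman")
  fit <- stats::coef(stats::lm(y ~ x))
  structure(
    list(spearman_rho = rho, ols_slope = unname(fit[2L]),
         ols_intercept = unname(fit[1L]), n_pairs = length(x)),
    class = "association_report"
  )
}

#' Cohen's d with two-tailed independent-samples t-test
#'
#' Effect size uses the df-weighted pooled standard deviation. The t-test is
#' the classical pooled-variance (Student) form by default; set
#' `welch = TRUE` for the unequal-variance form. The Bonferroni-adjusted p is
#' `min(1, p * n_comparisons)`.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2; missing values
#'   dropped).
#' @param n_comparisons Number of comparisons for the Bonferroni correction.
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return Object of class `association_report`: `cohens_d`, `t_statistic`,
#'   `p_value`, `p_adjusted`, `n_pairs` (total n).
#' @export
cohens_d_ttest <- function(group_a, group_b, n_comparisons = 1L,
                           welch = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_thetapet("thetapet_validation_error", "both groups need n >= 2")
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    warning("zero pooled variance; Cohen's d undefined")
    d <- NA_real_; tt <- list(statistic = NA_real_, p.value = if (mean(a) == mean(b)) 1 else 0)
  } else {
    d <- (mean(a) - mean(b)) / sqrt(sp2)
    tt <- stats::t.test(a, b, var.equal = !welch)
  }
  structure(
    list(cohens_d = d, t_statistic = unname(tt$statistic),
         p_value = tt$p.value,
         p_adjusted = min(1, tt$p.value * n_comparisons),
         n_pairs = length(a) + length(b)),
    class = "association_report"
  )
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the mean-squares decomposition of the participants x runs
#' score matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-participant, \eqn{MS_C} the between-run and
#' \eqn{MS_E} the residual mean square.
#'
#' @param score_matrix Numeric matrix, participants (>= 3) x runs (>= 2).
#' @return ICC value; `NA` with a warning for a constant matrix.
#' @export
icc_across_runs <- function(score_matrix) {
  M <- as.matrix(score_matrix)
  n <- nrow(M); k <- ncol(M)
  if (n < 3L || k < 2L) {
    stop_thetapet("thetapet_validation_error",
                  "need >= 3 participants and >= 2 runs")
  }
  if (stats::sd(as.numeric(M)) == 0) {
    warning("constant score matrix; ICC undefined")
    return(NA_real_)
  }
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((M - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
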