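# 2-region cohort that is linearly separable in the 'a' region
separable_cohort <- function(n = 400, seed = 31, shuffle_labels = FALSE) {
  at <- atlas_config(c("a", "b"),
                     meta_roi_membership = list(temporal = c("a", "b"),
                                                mtl = c("a", "b"),
                                                neo = c("a", "b")))
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.35)
    suvr <- cbind(a = 1.0 + 0.8 * y + runif(n, 0, 0.3),
                  b = runif(n, 0.9, 1.2))
    if (shuffle_labels) y <- sample(y)
    meta <- data.frame(participant_id = sprintf("S%04d", 1:n),
                       visual_rating = y)
    cohort_table(meta, suvr, at)
  })
}

flat_concordance <- function(cohort) {
  data.frame(participant_id = cohort$meta$participant_id,
             concordance = "concordant", pattern = "")
}

test_that("stratified split preserves per-stratum proportions within one", {
  co <- generate_cohort(simulation_config(n = 1290, seed = 37))
  cc <- label_concordance(co)
  sp <- stratified_split(co, cc, test_fraction = 0.20, seed = 4)
  expect_setequal(c(sp$train_ids, sp$test_ids), co$meta$participant_id)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # cohort-level 80/20
  expect_lte(abs(length(sp$test_ids) - round(0.20 * 1290)),
             nrow(sp$strata))
  for (i in seq_len(nrow(sp$strata))) {
    s <- sp$strata[i, ]
    if (s$n > 1) expect_lt(abs(s$n_test - 0.20 * s$n), 1)
  }
  # determinism
  sp2 <- stratified_split(co, cc, test_fraction = 0.20, seed = 4)
  expect_identical(sp$test_ids, sp2$test_ids)
})

test_that("singleton strata are assigned to training", {
  co <- separable_cohort(n = 10, seed = 41)
  co$meta$visual_rating <- c(1L, rep(0L, 9))
  sp <- stratified_split(co, flat_concordance(co), 0.2, seed = 1)
  lone <- co$meta$participant_id[1]
  expect_true(lone %in% sp$train_ids)
})

test_that("invalid split fractions are rejected", {
  co <- separable_cohort(n = 20)
  expect_error(stratified_split(co, flat_concordance(co), 0, seed = 1),
               class = "thetapet_config_error")
  expect_error(stratified_split(co, flat_concordance(co), 1, seed = 1),
               class = "thetapet_config_error")
})

test_that("ensemble separates a separable cohort and records its structure", {
  co <- separable_cohort(n = 400)
  sp <- stratified_split(co, flat_concordance(co), 0.2, seed = 2)
  md <- train_ensemble(co, sp, k = 5, repeats = 2, seed = 2, nrounds = 30)
  expect_equal(md$fit_metadata$n_base_learners, 10L)
  te <- match(sp$test_ids, co$meta$participant_id)
  p <- predict_proba(md, co$suvr[te, , drop = FALSE])
  expect_true(all(p >= 0 & p <= 1))
  m <- classification_metrics(co$meta$visual_rating[te],
                              as.integer(p > 0.5), p)
  expect_gte(m$balanced_accuracy, 0.95)
  # every fold partition covers each training row exactly once
  for (fold in md$fit_metadata$fold_ids) {
    expect_equal(sort(unique(fold)), 1:5)
    expect_length(fold, length(sp$train_ids))
  }
})

test_that("shuffled labels give chance-level performance", {
  accs <- vapply(1:3, function(i) {
    co <- separable_cohort(n = 400, seed = 50 + i, shuffle_labels = TRUE)
    sp <- stratified_split(co, flat_concordance(co), 0.2, seed = i)
    md <- train_ensemble(co, sp, k = 5, repeats = 1, seed = i, nrounds = 30)
    te <- match(sp$test_ids, co$meta$participant_id)
    p <- predict_proba(md, co$suvr[te, , drop = FALSE])
    classification_metrics(co$meta$visual_rating[te],
                           as.integer(p > 0.5), p)$balanced_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.40)
  expect_lte(mean(accs), 0.60)
})

test_that("single-class training sets are refused", {
  co <- separable_cohort(n = 60)
  co$meta$visual_rating <- rep(0L, 60)
  sp <- stratified_split(co, flat_concordance(co), 0.2, seed = 1)
  expect_error(train_ensemble(co, sp, seed = 1),
               class = "thetapet_training_error")
})

test_that("predictions are deterministic and order/naming invariant", {
  fit <- demo_fit()
  md <- fit$model; co <- fit$cohort
  X <- co$suvr[1:10, , drop = FALSE]
  expect_identical(predict_proba(md, X), predict_proba(md, X))
  # row order invariance
  perm <- c(7, 2, 9, 1, 3, 10, 4, 8, 5, 6)
  expect_equal(predict_proba(md, X[perm, ]), predict_proba(md, X)[perm])
  # column (region) order invariance via name matching
  shuf <- withr::with_seed(5, sample(ncol(X)))
  expect_equal(predict_proba(md, X[, shuf]), predict_proba(md, X))
  # single named panel
  expect_equal(predict_proba(md, X[1, ]), predict_proba(md, X)[1])
  # mismatched features are listed
  expect_error(predict_proba(md, X[, -5]), "missing",
               class = "thetapet_feature_error")
})

test_that("status threshold is strict-greater with sensible boundaries", {
  fit <- demo_fit()
  md <- fit$model
  p <- predict_proba(md, fit$cohort$suvr[1:20, ])
  expect_identical(predict_status(md, fit$cohort$suvr[1:20, ], threshold = 1.0),
                   rep(0L, 20))
  expect_identical(predict_status(md, fit$cohort$suvr[1:20, ], threshold = 0),
                   as.integer(p > 0))
  # p == threshold is negative
  expect_identical(as.integer(p > p), rep(0L, 20))
})

test_that("repeated runs are deterministic and validated", {
  co <- separable_cohort(n = 300)
  expect_error(repeated_runs(co, n_runs = 1, base_seed = 1,
                             concordance = flat_concordance(co)),
               class = "thetapet_config_error")
  r1 <- repeated_runs(co, n_runs = 3, base_seed = 9, k = 3, repeats = 1,
                      nrounds = 20, concordance = flat_concordance(co))
  r2 <- repeated_runs(co, n_runs = 3, base_seed = 9, k = 3, repeats = 1,
                      nrounds = 20, concordance = flat_concordance(co))
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(nrow(r1$metrics), 3L)
  expect_true(all(r1$metrics$balanced_accuracy >= 0.9))
})

test_that("model artifacts round-trip predictions bit-identically", {
  fit <- demo_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$model, path, config_hash = "abc123")
  re <- load_model(path)
  X <- fit$cohort$suvr[1:25, ]
  expect_identical(predict_proba(re, X), predict_proba(fit$model, X))
  expect_identical(re$config_hash, "abc123")
})
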