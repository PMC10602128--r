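#' Iterative stratified train/test split
#'
#' Splits a cohort into train and test sets while preserving, within one
#' participant, the test share of every joint stratum of visual status by
#' concordance group. Allocation is iterative-proportional: each stratum gets
#' `floor(n_s * test_fraction)` test slots and the remaining slots (to reach
#' the cohort-level target) go to the strata with the largest fractional
#' remainders; membership within a stratum is then sampled with a seeded RNG.
#' Singleton strata are always assigned to the training set.
#'
#' @param cohort A `cohort_table` with `visual_rating` present for everyone.
#' @param concordance Concordance labels from [label_concordance()]; computed
#'   from the default meta-ROI configuration when `NULL`.
#' @param test_fraction Proportion held out, in (0, 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return Object of class `split_spec` with `train_ids`, `test_ids`,
#'   `test_fraction`, `seed` and the per-stratum allocation table.
#' @export
stratified_split <- function(cohort, concordance = NULL, test_fraction = 0.20,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_thetapet("thetapet_config_error", "test_fraction must be in (0, 1)")
  }
  if (!"visual_rating" %in% names(cohort$meta) ||
      anyNA(cohort$meta$visual_rating)) {
    stop_thetapet("thetapet_validation_error",
                  "visual_rating must be present for all participants")
  }
  if (is.null(concordance)) concordance <- label_concordance(cohort)
  ids <- cohort$meta$participant_id
  conc <- concordance$concordance[match(ids, concordance$participant_id)]
  strata <- paste(cohort$meta$visual_rating, conc, sep = "/")
  tab <- table(strata)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  eligible <- sizes > 1L          # singleton strata stay in train
  target_total <- round(sum(sizes[eligible]) * test_fraction)
  base <- floor(sizes * test_fraction)
  base[!eligible] <- 0L
  frac <- sizes * test_fraction - base
  frac[!eligible] <- -1
  extra <- target_total - sum(base)
  alloc <- base
  if (extra > 0L) {
    ord <- order(frac, sizes, decreasing = TRUE)
    take <- ord[seq_len(min(extra, sum(eligible)))]
    alloc[take] <- alloc[take] + 1L
  }
  test_ids <- character(0)
  for (s in names(sizes)) {
    if (alloc[[s]] == 0L) next
    members <- ids[strata == s]
    pick <- with_seed(derive_seed(seed, match(s, names(sizes))),
                      sample(members, alloc[[s]]))
    test_ids <- c(test_ids, pick)
  }
  train_ids <- setdiff(ids, test_ids)
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         test_fraction = test_fraction, seed = as.integer(seed),
         strata = data.frame(stratum = names(sizes), n = sizes,
                             n_test = alloc, row.names = NULL)),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (test_fraction = %.2f, seed = %d)\n",
              length(x$train_ids), length(x$test_ids), x$test_fraction, x$seed))
  print(x$strata)
  invisible(x)
}

xgb_params <- function(seed) {
  list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
       subsample = 1, colsample_bytree = 1, nthread = 1,
       seed = as.integer(seed %% 2147483647))
}

stack_features <- function(per_repeat) {
  # per_repeat: n x repeats matrix of out-of-fold (or bagged) probabilities.
  # With a single repeat the combiner also sees the logit so the regularized
  # fit has two informative columns.
  if (ncol(per_repeat) == 1L) {
    p <- pmin(pmax(per_repeat[, 1L], 1e-6), 1 - 1e-6)
    per_repeat <- cbind(per_repeat, stats::qlogis(p))
  }
  colnames(per_repeat) <- paste0("s", seq_len(ncol(per_repeat)))
  per_repeat
}

#' Train the bagged, stacked tau-positivity ensemble
#'
#' Base layer: `k x repeats` gradient-boosted tree models, each repeat
#' partitioning the training rows into `k` class-stratified folds and fitting
#' one model per held-out fold on the complementary `k - 1` folds. The models
#' of a repeat are bagged by averaging. Stacking layer: a ridge-regularized
#' logistic combiner fitted on the strictly out-of-fold predictions (no base
#' learner ever scores a row it was fitted on when building combiner inputs).
#'
#' @param cohort A `cohort_table` with `visual_rating`.
#' @param split [stratified_split()] result.
#' @param k Number of folds per repeat.
#' @param repeats Number of bagging repeats.
#' @param seed Integer seed controlling fold assignment.
#' @param nrounds Boosting rounds per base learner.
#' @return Object of class `tau_classifier` holding the fitted base learners,
#'   the combiner, `feature_order`, training prevalence and `fit_metadata`
#'   (seed, fold scheme, `n_base_learners = k * repeats`).
#' @export
train_ensemble <- function(cohort, split, k = 5L, repeats = 2L, seed = 1L,
                           nrounds = 50L) {
  ids <- cohort$meta$participant_id
  tr <- match(split$train_ids, ids)
  if (anyNA(tr)) {
    stop_thetapet("thetapet_integrity_error", "split ids not in cohort")
  }
  X <- cohort$suvr[tr, , drop = FALSE]
  y <- cohort$meta$visual_rating[tr]
  if (length(unique(y)) < 2L) {
    stop_thetapet("thetapet_training_error",
                  "training set contains a single class")
  }
  n <- nrow(X)
  oof <- matrix(NA_real_, n, repeats)
  boosters <- vector("list", repeats)
  fold_ids <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- with_seed(derive_seed(seed, 1000L * r + cls), sample(idx))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold_ids[[r]] <- fold
    boosters[[r]] <- vector("list", k)
    for (j in seq_len(k)) {
      in_fold <- fold == j
      dtrain <- xgboost::xgb.DMatrix(X[!in_fold, , drop = FALSE],
                                     label = y[!in_fold])
      bst <- xgboost::xgb.train(
        params = xgb_params(derive_seed(seed, 100L * r + j)),
        data = dtrain, nrounds = nrounds, verbose = 0
      )
      boosters[[r]][[j]] <- bst
      # out-of-fold discipline: model j only ever scores its held-out fold
      oof[in_fold, r] <- stats::predict(
        bst, xgboost::xgb.DMatrix(X[in_fold, , drop = FALSE]))
    }
  }
  sf <- stack_features(oof)
  stacker <- glmnet::glmnet(sf, y, family = "binomial", alpha = 0,
                            lambda = 1e-3, standardize = TRUE)
  structure(
    list(base_learners = boosters, stacker = stacker,
         feature_order = colnames(cohort$suvr),
         training_prevalence = mean(y),
         threshold = 0.5,
         fit_metadata = list(seed = as.integer(seed), k = as.integer(k),
                             repeats = as.integer(repeats),
                             n_base_learners = as.integer(k) * as.integer(repeats),
                             nrounds = as.integer(nrounds),
                             n_train = n, fold_ids = fold_ids)),
    class = "tau_classifier"
  )
}

#' @export
print.tau_classifier <- function(x, ...) {
  md <- x$fit_metadata
  cat(sprintf(
    "<tau_classifier> %d base learners (k = %d x repeats = %d), %d features\n",
    md$n_base_learners, md$k, md$repeats, length(x$feature_order)))
  cat(sprintf("  training prevalence: %.3f; threshold: %.2f\n",
              x$training_prevalence, x$threshold))
  invisible(x)
}

as_feature_matrix <- function(model, newdata) {
  fo <- model$feature_order
  if (inherits(newdata, "cohort_table")) {
    X <- newdata$suvr
  } else if (is.numeric(newdata) && !is.matrix(newdata)) {
    X <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  } else {
    X <- as.matrix(newdata)
  }
  if (is.null(colnames(X))) {
    if (ncol(X) != length(fo)) {
      stop_thetapet("thetapet_feature_error",
                    "unnamed input has %d columns; model expects %d",
                    ncol(X), length(fo))
    }
    colnames(X) <- fo
  }
  missing <- setdiff(fo, colnames(X))
  extra <- setdiff(colnames(X), fo)
  if (length(missing) || length(extra)) {
    stop_thetapet("thetapet_feature_error",
                  "feature mismatch; missing: [%s], unexpected: [%s]",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", "))
  }
  X[, fo, drop = FALSE]
}

#' Predict tau-positivity probability
#'
#' Averages each repeat's `k` base learners, then applies the stacking
#' combiner. Input regions may appear in any order; they are matched to the
#' model's feature order by name.
#'
#' @param model A `tau_classifier`.
#' @param newdata Named SUVR vector, matrix/data.frame of panels with region
#'   column names, or a `cohort_table`.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, newdata) {
  X <- as_feature_matrix(model, newdata)
  dm <- xgboost::xgb.DMatrix(X)
  repeats <- length(model$base_learners)
  per_repeat <- matrix(0, nrow(X), repeats)
  for (r in seq_len(repeats)) {
    preds <- vapply(model$base_learners[[r]],
                    function(b) stats::predict(b, dm), numeric(nrow(X)))
    if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
    per_repeat[, r] <- rowMeans(preds)
  }
  p <- stats::predict(model$stacker, stack_features(per_repeat),
                      type = "response")[, 1L]
  unname(pmin(pmax(p, 0), 1))
}

#' Predict binary tau status
#'
#' Positive iff the predicted probability strictly exceeds the threshold.
#'
#' @inheritParams predict_proba
#' @param threshold Probability operating point (default 0.5).
#' @return Integer vector of 0/1 statuses.
#' @export
predict_status <- function(model, newdata, threshold = model$threshold) {
  as.integer(predict_proba(model, newdata) > threshold)
}

#' Repeated train/evaluate runs under different data splits
#'
#' Re-splits, re-trains and re-evaluates the ensemble `n_runs` times, run `i`
#' using seed `base_seed + i`. Used to assess the stability of the test
#' metrics and the repeatability (ICC) of downstream scores.
#'
#' @param cohort A `cohort_table`.
#' @param n_runs Number of runs (>= 2).
#' @param base_seed Integer base seed.
#' @param test_fraction,k,repeats,nrounds Passed to the split/training steps.
#' @param concordance Optional precomputed [label_concordance()] table.
#' @return List with `models` (per-run `tau_classifier`), `splits`, and
#'   `metrics` (one row per run: balanced accuracy, MCC, precision, recall,
#'   F1, ROC AUC on that run's test set).
#' @export
repeated_runs <- function(cohort, n_runs = 10L, base_seed = 1L,
                          test_fraction = 0.20, k = 5L, repeats = 2L,
                          nrounds = 50L, concordance = NULL) {
  if (n_runs < 2L) {
    stop_thetapet("thetapet_config_error", "n_runs must be >= 2")
  }
  if (is.null(concordance)) concordance <- label_concordance(cohort)
  models <- vector("list", n_runs)
  splits <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    s <- base_seed + i
    sp <- stratified_split(cohort, concordance, test_fraction, seed = s)
    md <- train_ensemble(cohort, sp, k = k, repeats = repeats, seed = s,
                         nrounds = nrounds)
    te <- match(sp$test_ids, cohort$meta$participant_id)
    prob <- predict_proba(md, cohort$suvr[te, , drop = FALSE])
    mr <- classification_metrics(cohort$meta$visual_rating[te],
                                 as.integer(prob > md$threshold), prob)
    models[[i]] <- md
    splits[[i]] <- sp
    rows[[i]] <- data.frame(run = i, seed = s,
                            balanced_accuracy = mr$balanced_accuracy,
                            mcc = mr$mcc, precision = mr$precision,
                            recall = mr$recall, f1 = mr$f1,
                            roc_auc = mr$roc_auc)
  }
  list(models = models, splits = splits, metrics = do.call(rbind, rows))
}

#' Serialize a trained ensemble to a single artifact file
#'
#' Boosters are stored as raw byte payloads so that reloading reproduces
#' predictions bit-identically.
#'
#' @param model A `tau_classifier`.
#' @param path Output file path.
#' @param config_hash Optional hash string recorded with the artifact.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, config_hash = NA_character_) {
  raw_layers <- lapply(model$base_learners, function(rep_models) {
    lapply(rep_models, xgboost::xgb.save.raw)
  })
  payload <- model
  payload$base_learners <- raw_layers
  payload$config_hash <- config_hash
  saveRDS(payload, path)
  invisible(path)
}

#' Load an ensemble saved by [save_model()]
#' @param path Artifact file path.
#' @return A `tau_classifier`.
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  payload$base_learners <- lapply(payload$base_learners, function(rep_models) {
    lapply(rep_models, xgboost::xgb.load.raw)
  })
  class(payload) <- "tau_classifier"
  payload
}
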