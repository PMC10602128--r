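#' Default pipeline configuration
#'
#' One nested list drives the whole workflow; it round-trips through YAML via
#' [read_pipeline_config()] / [write_pipeline_config()]. Sections: `seed`,
#' `simulation`, `meta_roi`, `split`, `training`, `shap`, `theta`.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 20260101L,
    simulation = list(n = 2000L, positive_fraction = 0.19,
                      baseline_mean = 1.05, baseline_sd = 0.05),
    meta_roi = list(temporal_cutoff = 1.23, mtl_cutoff = 1.30,
                    neo_cutoff = 1.73),
    split = list(test_fraction = 0.20),
    training = list(k = 5L, repeats = 2L, nrounds = 50L),
    shap = list(method = "sampled", scope = "all", n_permutations = 16L,
                n_background = 40L),
    theta = list(lower_percentile = 1, upper_percentile = 99,
                 percentile_scope = "per_scan")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file (YAML), merged over the defaults
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_thetapet("thetapet_config_error", "config file not found: %s", path)
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Table-style agreement block: visual rating vs meta-ROIs vs model
#'
#' One [confusion_rates()] row per comparator (temporal, MTL, NEO meta-ROI
#' statuses and the model's predicted status), with the visual rating as
#' reference.
#'
#' @param visual 0/1 visual ratings.
#' @param meta Meta-ROI table from [meta_roi_table()] aligned with `visual`.
#' @param model_status Optional 0/1 model predictions.
#' @return data.frame with one row per comparison (TPR, TNR, TP, TN and the
#'   2-decimal mismatch percentages).
#' @export
agreement_block <- function(visual, meta, model_status = NULL) {
  comparators <- list(temporal = meta$temporal_pos, mtl = meta$mtl_pos,
                      neo = meta$neo_pos)
  if (!is.null(model_status)) comparators$model <- model_status
  rows <- lapply(names(comparators), function(nm) {
    cr <- confusion_rates(visual, comparators[[nm]])
    data.frame(comparison = paste0("visual_vs_", nm),
               tpr = round(cr$tpr, 2), tnr = round(cr$tnr, 2),
               tp = cr$tp, tn = cr$tn,
               pos_mismatch_pct = cr$pos_mismatch_pct,
               neg_mismatch_pct = cr$neg_mismatch_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stage_time <- function(timings, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  list(result = res, timings = timings)
}

#' Run the full THETA workflow
#'
#' simulate (or load) -> meta-ROI -> concordance -> stratified split ->
#' ensemble training -> prediction -> Shapley attribution -> THETA ->
#' evaluation. All outputs (cohort tables, model artifact, score table,
#' agreement block, association summary, manifest) are written under
#' `out_dir`; identical config and seed give identical score tables.
#'
#' @param config Configuration list from [read_pipeline_config()] /
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-built `cohort_table`; when `NULL` a synthetic
#'   cohort is generated from `config$simulation`.
#' @param seed Optional override of `config$seed`.
#' @return Run manifest (list): config hash, seed, stage timings, file paths,
#'   and the in-memory results (`cohort`, `model`, `scores`, `evaluation`).
#' @export
run_full_pipeline <- function(config = default_pipeline_config(),
                              out_dir = tempfile("thetapet_run_"),
                              cohort = NULL, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  hash <- config_hash(config)

  st <- stage_time(timings, "simulate", {
    if (is.null(cohort)) {
      sim <- config$simulation
      generate_cohort(simulation_config(
        n = sim$n, seed = derive_seed(config$seed, 1L),
        baseline_mean = sim$baseline_mean, baseline_sd = sim$baseline_sd,
        positive_fraction = sim$positive_fraction))
    } else cohort
  })
  cohort <- st$result; timings <- st$timings
  paths <- list(
    suvr = file.path(out_dir, "cohort_suvr.csv"),
    metadata = file.path(out_dir, "cohort_metadata.csv"),
    model = file.path(out_dir, "model.rds"),
    scores = file.path(out_dir, "scores.csv"),
    agreement = file.path(out_dir, "agreement.csv"),
    associations = file.path(out_dir, "associations.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_cohort(cohort, paths$suvr, paths$metadata)

  mcfg <- meta_roi_config(config$meta_roi$temporal_cutoff,
                          config$meta_roi$mtl_cutoff,
                          config$meta_roi$neo_cutoff)
  st <- stage_time(timings, "meta_roi", meta_roi_table(cohort, mcfg))
  meta <- st$result; timings <- st$timings
  conc <- label_concordance(cohort, meta)

  st <- stage_time(timings, "train", {
    sp <- stratified_split(cohort, conc, config$split$test_fraction,
                           seed = derive_seed(config$seed, 2L))
    md <- train_ensemble(cohort, sp, k = config$training$k,
                         repeats = config$training$repeats,
                         seed = derive_seed(config$seed, 3L),
                         nrounds = config$training$nrounds)
    list(split = sp, model = md)
  })
  split <- st$result$split; model <- st$result$model; timings <- st$timings
  save_model(model, paths$model, config_hash = hash)

  st <- stage_time(timings, "predict", predict_proba(model, cohort))
  prob <- st$result; timings <- st$timings
  status <- as.integer(prob > model$threshold)

  scope_ids <- if (identical(config$shap$scope, "test")) split$test_ids
               else cohort$meta$participant_id
  scope_idx <- match(scope_ids, cohort$meta$participant_id)
  scope_cohort <- cohort_table(cohort$meta[scope_idx, , drop = FALSE],
                               cohort$suvr[scope_idx, , drop = FALSE],
                               atlas = cohort$atlas,
                               provenance = cohort$provenance)
  train_cohort <- cohort_table(
    cohort$meta[match(split$train_ids, cohort$meta$participant_id), , drop = FALSE],
    cohort$suvr[match(split$train_ids, cohort$meta$participant_id), , drop = FALSE],
    atlas = cohort$atlas, provenance = cohort$provenance)

  st <- stage_time(timings, "explain", {
    bg <- shap_background(train_cohort, config$shap$n_background,
                          seed = derive_seed(config$seed, 4L))
    attribution_matrix(model, scope_cohort, bg, method = config$shap$method,
                       n_permutations = config$shap$n_permutations,
                       seed = derive_seed(config$seed, 5L))
  })
  shap <- st$result; timings <- st$timings

  tcfg <- theta_config(config$theta$lower_percentile,
                       config$theta$upper_percentile,
                       config$theta$percentile_scope)
  st <- stage_time(timings, "score", batch_theta(shap, scope_cohort, tcfg))
  theta_tab <- st$result; timings <- st$timings

  st <- stage_time(timings, "evaluate", {
    block <- agreement_block(cohort$meta$visual_rating, meta, status)
    te <- match(split$test_ids, cohort$meta$participant_id)
    test_metrics <- classification_metrics(
      cohort$meta$visual_rating[te], status[te], prob[te])
    sm <- scope_cohort$meta
    tt <- theta_tab[match(sm$participant_id, theta_tab$participant_id), ]
    assoc <- rbind(
      data.frame(measure = "mmse", t(unlist(
        spearman_ols(tt$theta, sm$mmse)[c("spearman_rho", "ols_slope",
                                          "ols_intercept", "n_pairs")]))),
      data.frame(measure = "cdr_sb", t(unlist(
        spearman_ols(tt$theta, sm$cdr_sb)[c("spearman_rho", "ols_slope",
                                            "ols_intercept", "n_pairs")])))
    )
    d_theta <- cohens_d_ttest(tt$theta[sm$visual_rating == 1],
                              tt$theta[sm$visual_rating == 0])
    mm <- meta[match(sm$participant_id, meta$participant_id), ]
    d_temporal <- cohens_d_ttest(mm$temporal_suvr[sm$visual_rating == 1],
                                 mm$temporal_suvr[sm$visual_rating == 0])
    list(agreement = block, test_metrics = test_metrics, associations = assoc,
         cohens_d = data.frame(score = c("theta", "temporal_suvr"),
                               d = c(d_theta$cohens_d, d_temporal$cohens_d)))
  })
  evaluation <- st$result; timings <- st$timings

  results <- data.frame(
    participant_id = cohort$meta$participant_id,
    meta[match(cohort$meta$participant_id, meta$participant_id),
         c("temporal_suvr", "mtl_suvr", "neo_suvr",
           "temporal_pos", "mtl_pos", "neo_pos")],
    concordance = conc$concordance[match(cohort$meta$participant_id,
                                         conc$participant_id)],
    predicted_probability = prob,
    predicted_status = status,
    stringsAsFactors = FALSE
  )
  results <- merge(results, theta_tab, by = "participant_id",
                   all.x = TRUE, sort = FALSE)
  write_scores(cohort, results, paths$scores)
  utils::write.table(evaluation$agreement, paths$agreement, sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(evaluation$associations, paths$associations, sep = ",",
                     row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("thetapet")),
    config_hash = hash, seed = config$seed,
    timings_sec = timings,
    files = lapply(paths, normalizePath, mustWork = FALSE)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  for (p in paths) {
    if (!file.exists(p)) {
      stop_thetapet("thetapet_pipeline_error", "missing output file: %s", p)
    }
  }
  invisible(c(manifest,
              list(cohort = cohort, model = model, split = split,
                   scores = results, theta = theta_tab, shap = shap,
                   evaluation = evaluation)))
}
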