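#' Deposition archetypes for the synthetic cohort generator
#'
#' Each archetype is a mean SUVR elevation pattern over the atlas regions,
#' chosen so that the default meta-ROI cutoffs (1.23 / 1.30 / 1.73) split the
#' archetypes into the visual/meta-ROI concordant and discordant groups seen
#' in heterogeneous tau-PET cohorts:
#' \describe{
#'   \item{diffuse}{elevation across temporal, parietal and occipital cortex
#'     exceeding all three cutoffs; visually positive and fully concordant.}
#'   \item{neocortical}{strong middle/inferior temporal elevation (NEO+,
#'     MTL-); visually positive, hence discordant with the MTL call.}
#'   \item{mtl_predominant}{isolated entorhinal/amygdala elevation (MTL+ only).
#'     Visual reads call isolated mesial temporal activity negative, so these
#'     scans are visually negative and discordant.}
#'   \item{focal_atypical}{occipital/parietal elevation sparing the temporal
#'     meta-ROI members; visually positive with all meta-ROIs negative
#'     (the pattern meta-ROIs miss).}
#'   \item{negative}{no elevation anywhere; visually negative, concordant.}
#' }
#'
#' Prevalences are the shares of the tau-positive archetypes conditional on a
#' participant being archetype-positive; they sum to 1. The negative archetype
#' has zero mean shift everywhere and occupies the remaining
#' `1 - positive_fraction` of the cohort.
#'
#' @return Named list of archetype specifications (`name`, `mean_shift`,
#'   `within_subject_sd`, `prevalence`, `visual_rating`).
#' @export
default_archetypes <- function() {
  shift <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  temporal6 <- c("entorhinal", "amygdala", "parahippocampal", "fusiform",
                 "inferior_temporal", "middle_temporal")
  assoc <- c("superior_temporal", "bankssts", "inferior_parietal",
             "superior_parietal", "supramarginal", "precuneus",
             "posterior_cingulate", "isthmus_cingulate", "lateral_occipital",
             "lingual", "cuneus", "pericalcarine", "temporal_pole",
             "transverse_temporal")
  frontal <- c("caudal_middle_frontal", "rostral_middle_frontal",
               "superior_frontal", "lateral_orbitofrontal",
               "medial_orbitofrontal", "pars_opercularis",
               "pars_triangularis", "insula")
  list(
    diffuse = list(
      name = "diffuse",
      mean_shift = shift(stats::setNames(rep(0.80, 6), temporal6),
                         stats::setNames(rep(0.55, length(assoc)), assoc),
                         stats::setNames(rep(0.35, length(frontal)), frontal)),
      within_subject_sd = 0.08, prevalence = 0.60, visual_rating = 1L),
    neocortical = list(
      name = "neocortical",
      mean_shift = shift(middle_temporal = 0.85, inferior_temporal = 0.85,
                         superior_temporal = 0.30, bankssts = 0.30,
                         fusiform = 0.20),
      within_subject_sd = 0.08, prevalence = 0.14, visual_rating = 1L),
    mtl_predominant = list(
      name = "mtl_predominant",
      mean_shift = shift(entorhinal = 0.45, amygdala = 0.45,
                         hippocampus = 0.20),
      within_subject_sd = 0.08, prevalence = 0.12, visual_rating = 0L),
    focal_atypical = list(
      name = "focal_atypical",
      mean_shift = shift(lateral_occipital = 0.65, cuneus = 0.65,
                         pericalcarine = 0.60, lingual = 0.60,
                         superior_parietal = 0.60, inferior_parietal = 0.60,
                         precuneus = 0.55),
      within_subject_sd = 0.08, prevalence = 0.14, visual_rating = 1L),
    negative = list(
      name = "negative",
      mean_shift = shift(),
      within_subject_sd = 0.08, prevalence = NA_real_, visual_rating = 0L)
  )
}

#' Simulation configuration for synthetic tau-PET cohorts
#'
#' Defaults emulate a population-based cohort: 19% of participants carry a
#' tau-positive deposition archetype, regional SUVRs sit near 1.05 in the
#' absence of tau, and clinical scores degrade with realised tau burden.
#'
#' @param n Cohort size.
#' @param seed Integer seed; all randomness derives from it.
#' @param baseline_mean Baseline SUVR in the absence of deposition.
#' @param baseline_sd SD of the participant-level baseline intercept (shared
#'   across regions; induces inter-region correlation).
#' @param archetypes List as returned by [default_archetypes()].
#' @param positive_fraction Probability of drawing a tau-positive archetype.
#' @param clinical_link Slopes/noise mapping latent burden (mean regional
#'   elevation above baseline) to MMSE (29 - slope*burden, clipped to [0,30])
#'   and CDR-SB (slope*burden, clipped at 0).
#' @param atlas [atlas_config()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n = 2000, seed = 20260101,
                              baseline_mean = 1.05, baseline_sd = 0.05,
                              archetypes = default_archetypes(),
                              positive_fraction = 0.19,
                              clinical_link = list(mmse_slope = 19,
                                                   mmse_noise = 1.5,
                                                   cdr_slope = 11,
                                                   cdr_noise = 0.8),
                              atlas = atlas_config()) {
  if (n < 1) stop_thetapet("thetapet_config_error", "n must be >= 1")
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop_thetapet("thetapet_config_error", "positive_fraction must be in [0,1]")
  }
  if (baseline_sd <= 0) {
    stop_thetapet("thetapet_config_error", "baseline_sd must be > 0")
  }
  pos <- Filter(function(a) a$name != "negative", archetypes)
  prev <- vapply(pos, function(a) a$prevalence, numeric(1))
  if (length(pos) && abs(sum(prev) - 1) > 1e-8) {
    stop_thetapet("thetapet_config_error",
                  "positive archetype prevalences must sum to 1 (got %.4f)",
                  sum(prev))
  }
  neg <- Filter(function(a) a$name == "negative", archetypes)
  if (length(neg) && length(neg[[1L]]$mean_shift) > 0 &&
      any(neg[[1L]]$mean_shift != 0)) {
    stop_thetapet("thetapet_config_error",
                  "negative archetype must have zero mean shift")
  }
  for (a in archetypes) {
    if (a$within_subject_sd <= 0) {
      stop_thetapet("thetapet_config_error", "all sd must be > 0")
    }
    unknown <- setdiff(names(a$mean_shift), atlas$region_names)
    if (length(unknown)) {
      stop_thetapet("thetapet_config_error",
                    "archetype '%s' shifts unknown region(s): %s",
                    a$name, paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         archetypes = archetypes, positive_fraction = positive_fraction,
         clinical_link = clinical_link, atlas = atlas),
    class = "simulation_config"
  )
}

#' Generate a synthetic tau-PET cohort
#'
#' Each participant draws an archetype (negative with probability
#' `1 - positive_fraction`, otherwise among the positive archetypes by
#' prevalence). Regional SUVR = participant baseline intercept
#' `N(baseline_mean, baseline_sd)` + archetype mean shift + independent
#' `N(0, within_subject_sd)` region noise, floored at 0.5. The visual rating
#' follows the archetype: the negative archetype and the MTL-only pattern are
#' rated negative (isolated mesial temporal activity is visually negative),
#' all other positive archetypes are rated positive. MMSE and CDR-SB are
#' generated from the realised latent burden (mean regional elevation above
#' baseline) through `clinical_link`.
#'
#' @param config [simulation_config()].
#' @return A [cohort_table()] whose metadata includes the generating
#'   `archetype` column (for downstream subgrouping in tests and reports).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  atlas <- config$atlas
  m <- length(atlas$region_names)
  n <- config$n
  arche <- config$archetypes
  pos_names <- names(Filter(function(a) a$name != "negative", arche))
  prev <- vapply(arche[pos_names], function(a) a$prevalence, numeric(1))

  with_seed(config$seed, {
    is_pos <- stats::runif(n) < config$positive_fraction
    kind <- rep("negative", n)
    if (any(is_pos) && length(pos_names)) {
      kind[is_pos] <- sample(pos_names, sum(is_pos), replace = TRUE, prob = prev)
    }
    intercept <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    suvr <- matrix(0, n, m, dimnames = list(NULL, atlas$region_names))
    visual <- integer(n)
    for (i in seq_len(n)) {
      a <- arche[[kind[i]]]
      shift <- stats::setNames(rep(0, m), atlas$region_names)
      if (length(a$mean_shift)) shift[names(a$mean_shift)] <- a$mean_shift
      suvr[i, ] <- intercept[i] + shift +
        stats::rnorm(m, 0, a$within_subject_sd)
      visual[i] <- a$visual_rating
    }
    suvr[suvr < 0.5] <- 0.5

    burden <- rowMeans(suvr) - config$baseline_mean
    cl <- config$clinical_link
    mmse <- round(pmin(30, pmax(0, 29 - cl$mmse_slope * burden +
                                  stats::rnorm(n, 0, cl$mmse_noise))))
    cdr <- round(pmin(18, pmax(0, cl$cdr_slope * burden +
                                 stats::rnorm(n, 0, cl$cdr_noise))) * 2) / 2
    bn <- burden + stats::rnorm(n, 0, 0.04)
    diagnosis <- ifelse(bn < 0.08, "CU", ifelse(bn < 0.22, "MCI", "AD"))
    dlb <- stats::runif(n) < 0.03 & diagnosis != "CU"
    diagnosis[dlb] <- "DLB"
    amyloid <- as.integer(stats::runif(n) <
                            stats::plogis(20 * (burden - 0.03)) * 0.85 + 0.05)
    apoe4 <- as.integer(stats::runif(n) < 0.25 + 0.25 * amyloid)
    meta <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      visual_rating = visual,
      diagnosis = diagnosis,
      mmse = as.integer(mmse),
      cdr_sb = cdr,
      age = round(pmin(95, pmax(50, stats::rnorm(n, 70, 9))), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      amyloid_status = amyloid,
      apoe4 = apoe4,
      archetype = kind,
      stringsAsFactors = FALSE
    )
    cohort_table(meta, suvr, atlas = atlas, provenance = "synthetic")
  })
}
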