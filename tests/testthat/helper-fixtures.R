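# Shared fixtures: reduced atlases, toy cohorts, independent oracles, and a
# memoized demo fit reused across test files.

atlas8 <- function() {
  atlas_config(c("entorhinal", "amygdala", "parahippocampal", "fusiform",
                 "inferior_temporal", "middle_temporal", "precuneus",
                 "lateral_occipital"))
}

# small well-formed cohort on the full 41-region atlas
toy_cohort <- function(n = 3, seed = 1, atlas = atlas_config()) {
  m <- length(atlas$region_names)
  suvr <- withr::with_seed(seed,
    matrix(runif(n * m, 0.8, 1.4), n, m,
           dimnames = list(NULL, atlas$region_names)))
  meta <- data.frame(
    participant_id = sprintf("T%03d", seq_len(n)),
    visual_rating = withr::with_seed(seed + 1, rbinom(n, 1, 0.3)),
    diagnosis = "CU", mmse = 29L, cdr_sb = 0, age = 70, sex = "F",
    amyloid_status = 0L, apoe4 = 0L, stringsAsFactors = FALSE
  )
  cohort_table(meta, suvr, atlas = atlas, provenance = "toy")
}

# independent brute-force Shapley oracle: direct summation over all
# coalitions with explicit factorial weights and explicit background means
brute_shapley <- function(f, x, bg) {
  m <- length(x)
  v <- function(S) {
    Z <- bg
    for (j in S) Z[, j] <- x[j]
    mean(f(Z))
  }
  phi <- numeric(m)
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    for (s in 0:length(others)) {
      subsets <- if (s == 0) list(integer(0)) else
        apply(utils::combn(others, s), 2L, identity, simplify = FALSE)
      w <- factorial(s) * factorial(m - s - 1) / factorial(m)
      for (S in subsets) phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  stats::setNames(phi, names(x))
}

# independent THETA oracle: literal transcription of the score definition
brute_theta <- function(phi, x, lower = 1, upper = 99) {
  b <- stats::quantile(phi, c(lower, upper) / 100, type = 7, names = FALSE)
  inside <- phi >= b[1] & phi <= b[2]
  sum(phi) + sum(phi[inside] * x[inside])
}

# independent AUC oracle: concordant-pair counting with half credit for ties
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# memoized mid-sized synthetic fit shared by the shap/theta test files
.demo_cache <- new.env(parent = emptyenv())
demo_fit <- function() {
  if (is.null(.demo_cache$fit)) {
    cohort <- generate_cohort(simulation_config(n = 700, seed = 42))
    conc <- label_concordance(cohort)
    split <- stratified_split(cohort, conc, 0.2, seed = 5)
    model <- train_ensemble(cohort, split, k = 5, repeats = 2, seed = 5)
    .demo_cache$fit <- list(cohort = cohort, conc = conc, split = split,
                            model = model)
  }
  .demo_cache$fit
}

subset_cohort <- function(cohort, idx) {
  cohort_table(cohort$meta[idx, , drop = FALSE],
               cohort$suvr[idx, , drop = FALSE],
               atlas = cohort$atlas, provenance = cohort$provenance)
}
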