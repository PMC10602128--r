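Package: thetapet
Title: Heterogeneity-Aware Summary Scoring of Regional Tau-PET SUVR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies tau burden from regional tau-PET SUVR panels. Provides
    the temporal, medial-temporal (MTL) and neocortical (NEO) meta-ROI summary
    measures with published positivity cutoffs; a bagged, stacked ensemble
    classifier of visual tau-positivity trained on 41 regional SUVR values with
    iterative stratified splitting; exact and permutation-sampled Shapley
    attribution of the predicted positivity probability to individual regions;
    and the THETA summary score, a linear combination of the regional Shapley
    attributions and their SUVR-weighted contributions within a percentile band.
    Includes a synthetic cohort generator emulating heterogeneous tau deposition
    patterns (concordant and discordant with meta-ROI calls), agreement and
    effect-size statistics, rerun repeatability (ICC), and an end-to-end
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
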