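---
title: "Methods: tau-positivity classification and the THETA summary score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tau-positivity classification and the THETA summary score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `thetapet`, and what the synthetic-cohort test suite does and does not
establish about behaviour on real data.

## Inputs and data model

The package starts downstream of image processing: each participant
contributes 41 regional tau-PET SUVR values (median regional uptake,
referenced to cerebellar crus, averaged across hemispheres; unitless, all
values positive). A `cohort_table` pairs these panels with clinical metadata
(visual tau rating, diagnosis, MMSE 0–30, CDR-SB 0–18, age, sex, amyloid and
APOE4 status). Missing clinical values stay missing — association analyses
use complete pairs only, never imputation. Region order is fixed by the
`atlas_config`, never by file column order, so a model trained once scores
any correctly named table. Files are comma-delimited UTF-8 with a header
(tab accepted via `delim`), since no interchange format is standardized for
regional SUVR tables.

Whether the regional medians should enter before or after hemispheric
averaging is not decidable from the inputs this package accepts; the 41
averaged values are taken as given.

## Meta-ROI measures

Three composite measures with their conventional cutoffs:

| measure  | members                                                       | average         | cutoff (SUVR) |
|----------|---------------------------------------------------------------|-----------------|---------------|
| temporal | entorhinal, amygdala, parahippocampal, fusiform, inf./mid. temporal | voxel-weighted | 1.23 |
| MTL      | entorhinal, amygdala                                          | unweighted      | 1.30 |
| NEO      | middle temporal, inferior temporal                            | voxel-weighted  | 1.73 |

"Voxel-weighted" is resolved as weights proportional to configured region
volumes (`atlas_config(region_weights = ...)`): voxel counts are not
available downstream of regional extraction, and equal weights are the
shipped default with a documented override. All three cutoffs are applied
strict-greater; the boundary value is negative. Both choices are
configurable, and no data-driven cutoff re-estimation is provided.

## The tau-positivity ensemble

The classifier predicts the expert visual rating (the clinically accepted
reference) from the 41 SUVRs.

**Splitting.** Train/test splitting is iterative stratified over the joint
strata of visual status x concordance group (concordant scans agree with all
three meta-ROI calls). Each stratum receives `floor(n_s * f)` test slots plus
largest-remainder top-ups to the cohort-level target, so every stratum's test
share is within one participant of the target fraction; singleton strata go
to training. Membership is sampled with a seeded RNG — splits are
reproducible and "semi-random": the allocation is deterministic, only the
membership draw is random.

**Ensemble.** The base layer is `k x repeats` gradient-boosted tree models
(xgboost; depth 3, eta 0.3, 50 rounds, single thread for determinism), each
repeat partitioning the training rows into `k` class-stratified folds and
fitting one model per held-out fold. The stacking layer is a
ridge-regularized logistic combiner (glmnet, alpha 0, lambda 1e-3) fitted on
the strictly out-of-fold predictions, one column per repeat — no base
learner ever scores a row it was fitted on when building combiner inputs
(with a single repeat the combiner also receives the logit of the one
column). Defaults `k = 5`, `repeats = 2` give 10 base learners; the original
analysis delegated model selection to an automated framework whose exact
portfolio is unreported, so this small fixed portfolio was chosen for
reproducibility and speed. Class imbalance is handled by stratification
only. The operating point is 0.5 on the stacked probability (strict-greater),
since no operating point is conventionally stated; it is an argument of
`predict_status()`.

Model artifacts serialize boosters as raw byte payloads, so reloading
reproduces predictions bit-identically.

## Shapley attribution

Attribution targets the **positive-class probability**, not the hard label:
additivity `base_value + sum(phi) = p` then holds for every scan, and for
confidently classified scans the attributions sum to approximately -base or
1-base (the "sums to the label" picture corresponds to the saturated limit).
The value function is the interventional expectation: `v(S)` replaces the
regions in `S` with the explained panel's values across a background sample
and averages the model output. The background is a seeded subsample (default
100 rows) of the training set; the variant and background are recorded in the
output because neither is canonical.

`exact_shapley()` enumerates all `2^m` coalitions (feasible to `m = 15`) and
is the in-package oracle; an independent brute-force summation over
coalitions lives in the test suite. `sampled_shapley()` walks random feature
orderings, drawn in antithetic pairs (each ordering with its reverse) to
cancel first-order noise, and afterwards spreads the residual
`p - base - sum(phi)` evenly over the `m` regions so additivity holds
exactly. Renormalization shifts each attribution by at most the estimation
error, and makes downstream THETA decompositions exact. Estimator accuracy
is checked against exact enumeration (max deviation below 0.01 at 2000
permutations on an 8-region model); attribution of a 41-region cohort uses a
shared permutation stream across participants so background walks batch into
large matrix predictions.

## THETA

For one scan with attributions `phi` and SUVRs `x`:

    theta = sum(phi) + sum(phi_hat * x),   phi_hat = phi * inside_band

The first sum always runs over all `m` regions. The band is the 1st–99th
percentile of the attribution values (linear interpolation between order
statistics, `quantile(type = 7)`); regions outside it are excluded from the
second (SUVR-weighted) sum only. Two band scopes are implemented because the
definition is ambiguous between them: `per_scan` (default — the band is
computed over the scan's own 41 attributions, keeping the score computable
for a single participant) and `cohort_per_region` (per-region bands across
the cohort). The choice is recorded in the configuration and output. With
all values equal the band collapses onto the common value and every region
is included; with the band at 0–100 the score collapses to
`sum(phi * (1 + x))`, a closed form used as a test oracle.

The regional decomposition `theta_i = phi_i + phi_hat_i * x_i` is a
package-defined decomposition consistent with the score (regional
contributions are plotted in the source analysis without a printed
definition); it sums to `theta` exactly and drives the subgroup rankings in
`regional_theta_ranking()`. No normalization is applied to `theta`; its
scale mixes probability units (first sum) and probability x SUVR units
(second sum).

## Evaluation statistics

- Mismatch rates `1 - TPR`, `1 - TNR` against the visual reference, reported
  round-half-even to 2 decimals. Two published comparison cells (7.34, 4.97)
  appear truncated rather than rounded in print; the acceptance checks allow
  ±0.01 there and exact equality elsewhere.
- ROC AUC by midrank Mann–Whitney (equals the trapezoidal area with tied
  scores), cross-checked against brute-force pair counting and pROC.
- Cohen's d with df-weighted pooled SD; the t-test defaults to the
  pooled-variance Student form (the source analysis does not state an
  equal-variance assumption; Welch is available via `welch = TRUE`).
  Bonferroni adjustment is `min(1, p * n_comparisons)`.
- Repeatability uses ICC(2,1) — two-way random effects, absolute agreement,
  single measure — from the mean-squares decomposition, because the ICC
  variant is not conventionally fixed in this context; constant matrices
  return `NA` with a warning rather than 1.

## The synthetic cohort generator

The generator's defaults define the package's study conditions and are not
tuned per analysis: cohort baseline SUVR 1.05, participant-level intercept
SD 0.05 (shared across regions — the random intercept that induces
inter-region correlation), per-region noise SD 0.08, 19% archetype-positive
prevalence, and five deposition archetypes:

- **diffuse** (60% of positives): +0.80 SUVR on the six temporal meta-ROI
  members, +0.55 on temporo-parieto-occipital association cortex, +0.35
  frontal; exceeds all three cutoffs; visually positive, concordant.
- **neocortical** (14%): +0.85 on middle/inferior temporal (NEO+, MTL-);
  visually positive, discordant with the MTL call.
- **mtl_predominant** (12%): +0.45 on entorhinal/amygdala only (MTL+ only).
  Visual read criteria call isolated mesial temporal activity negative, so
  these scans are visually negative and discordant.
- **focal_atypical** (14%): +0.55 to +0.65 on occipital/parietal regions,
  sparing the temporal meta-ROI; visually positive with all meta-ROIs
  negative — the pattern composite measures miss.
- **negative**: zero shift everywhere.

Shift magnitudes were chosen once so the default cutoffs split the
archetypes as above (e.g. entorhinal/amygdala at ~1.50 clears the MTL cutoff
1.30 while keeping the temporal composite at ~1.20, below 1.23). MMSE is
`29 - 19*burden` and CDR-SB `11*burden` (burden = realized mean regional
elevation; Gaussian noise SDs 1.5 and 0.8, clipped to the scales' ranges),
giving MMSE around 22 and CDR-SB around 4 for diffuse-pattern carriers.
All randomness flows from one seed through deterministic per-stage
substreams.

**What passing tests do and do not show.** The generator reproduces the
*logical* structure the method relies on — heterogeneous patterns, all four
concordance/discordance cases, clinical scores monotone in burden — with
strong, well-separated effects. It does not emulate the real correlation
structure among the 41 regions (a single shared intercept is a stand-in),
scanner or site effects, rater disagreement, borderline scans, or
longitudinal change. Consequently the near-perfect synthetic classification
and the large effect sizes say the implementation is correct and the
pipeline is self-consistent, not that comparable performance would be
reached on patient data. One structural divergence is deliberate: because
the visual-rating rule makes the MTL-only pattern negative, the entorhinal
region is non-discriminative for the synthetic training target, and the
ensemble attributes (near) zero to it — on real cohorts, where mesial
temporal signal co-varies with true positivity more subtly, entorhinal
attributions are reported as prominent. The attribution tests therefore
assert the construction-guaranteed forms (negative-signal-driven decisions
for MTL-only scans; inferior temporal leading for neocortical scans; member
vs non-member mass contrasts between concordant and discordant positives).

## Problem sizes and numerical tolerances

Deterministic identities (exact-Shapley additivity, THETA closed form and
decomposition) are asserted at 1e-12 or tighter; renormalized sampled
additivity at 1e-12; exact-vs-brute-force Shapley at 1e-12. The package's
standing evaluation uses: a 2000-participant default cohort with 10
resplit/retrain runs for metric stability; 5 shuffled-label controls
(summarized by their mean, which at these test-set sizes estimates chance
level within about a point); ICC over the 10 reruns on a fixed 50-participant
subset scored with 16-permutation sampled attribution against 30 background
rows; additivity over a fully scored 500-participant cohort (50
permutations, 20 background rows, a 3-fold single-repeat ensemble); and a
150-participant subset for the effect-size contrast. These sizes were chosen
as the smallest at which the binomial/ICC noise is clearly away from the
asserted thresholds.

## Known limitations

- No image handling (DICOM/NIfTI), atlas propagation or coregistration; no
  re-derivation of meta-ROI cutoffs; no longitudinal modelling.
- Exact attribution is limited to 15 regions; the full panel always uses the
  sampled estimator.
- The sampled estimator's per-region error scales as
  `O(1/sqrt(n_permutations))`; 16 permutations are adequate for THETA-level
  summaries (the first component is exact after renormalization), while
  region-level inference should use several hundred.
- THETA's scale is model- and cohort-dependent (via the base value and
  attribution spread); scores are comparable within one trained model, not
  across models.
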