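#' Meta-ROI cutoff configuration
#'
#' Positivity cutoffs for the three meta-ROI summary SUVRs: 1.23 for the
#' temporal meta-ROI, 1.30 for the MTL, 1.73 for the NEO. A meta-ROI is called
#' positive when its SUVR is strictly greater than the cutoff.
#'
#' @param temporal_cutoff,mtl_cutoff,neo_cutoff Positive SUVR cutoffs.
#' @return An object of class `meta_roi_config`.
#' @export
meta_roi_config <- function(temporal_cutoff = 1.23, mtl_cutoff = 1.30,
                            neo_cutoff = 1.73) {
  cuts <- c(temporal = temporal_cutoff, mtl = mtl_cutoff, neo = neo_cutoff)
  if (any(!is.finite(cuts)) || any(cuts <= 0)) {
    stop_thetapet("thetapet_config_error", "all cutoffs must be > 0")
  }
  structure(as.list(cuts), class = "meta_roi_config")
}

panel_values <- function(panel, regions, atlas) {
  if (is.matrix(panel)) panel <- panel[1L, ]
  missing <- setdiff(regions, names(panel))
  if (length(missing)) {
    stop_thetapet("thetapet_validation_error",
                  "panel lacks meta-ROI member region(s): %s",
                  paste(missing, collapse = ", "))
  }
  panel[regions]
}

weighted_roi_mean <- function(panel, regions, atlas) {
  x <- panel_values(panel, regions, atlas)
  w <- atlas$region_weights[regions]
  sum(w * x) / sum(w)
}

#' Temporal meta-ROI SUVR
#'
#' Voxel-weighted average of the entorhinal, amygdala, parahippocampal,
#' fusiform, inferior temporal and middle temporal SUVRs, with weights taken
#' from `atlas$region_weights` (equal by default).
#'
#' @param panel Named numeric SUVR vector (one participant).
#' @param atlas [atlas_config()].
#' @return SUVR value.
#' @export
temporal_suvr <- function(panel, atlas = atlas_config()) {
  weighted_roi_mean(panel, atlas$meta_roi_membership$temporal, atlas)
}

#' MTL meta-ROI SUVR
#'
#' Unweighted mean of the entorhinal and amygdala SUVRs; region weights are
#' deliberately ignored.
#'
#' @inheritParams temporal_suvr
#' @return SUVR value.
#' @export
mtl_suvr <- function(panel, atlas = atlas_config()) {
  mean(panel_values(panel, atlas$meta_roi_membership$mtl, atlas))
}

#' NEO meta-ROI SUVR
#'
#' Voxel-weighted average of the middle temporal and inferior temporal SUVRs.
#'
#' @inheritParams temporal_suvr
#' @return SUVR value.
#' @export
neo_suvr <- function(panel, atlas = atlas_config()) {
  weighted_roi_mean(panel, atlas$meta_roi_membership$neo, atlas)
}

#' Meta-ROI SUVRs and positivity statuses for one panel
#'
#' @inheritParams temporal_suvr
#' @param cfg [meta_roi_config()] with the three cutoffs.
#' @return List of class `meta_roi_result` with fields `temporal_suvr`,
#'   `mtl_suvr`, `neo_suvr` and the strict-greater statuses `temporal_pos`,
#'   `mtl_pos`, `neo_pos` (0/1).
#' @export
classify_meta_roi <- function(panel, atlas = atlas_config(),
                              cfg = meta_roi_config()) {
  tmp <- temporal_suvr(panel, atlas)
  mtl <- mtl_suvr(panel, atlas)
  neo <- neo_suvr(panel, atlas)
  structure(
    list(temporal_suvr = tmp, mtl_suvr = mtl, neo_suvr = neo,
         temporal_pos = as.integer(tmp > cfg$temporal),
         mtl_pos = as.integer(mtl > cfg$mtl),
         neo_pos = as.integer(neo > cfg$neo)),
    class = "meta_roi_result"
  )
}

#' Meta-ROI table for a whole cohort
#'
#' Vectorised [classify_meta_roi()] over all participants.
#'
#' @param cohort A `cohort_table`.
#' @param cfg [meta_roi_config()].
#' @return data.frame with `participant_id`, the three SUVRs and the three
#'   0/1 statuses.
#' @export
meta_roi_table <- function(cohort, cfg = meta_roi_config()) {
  atlas <- cohort$atlas
  wm <- function(regions, weighted = TRUE) {
    sub <- cohort$suvr[, regions, drop = FALSE]
    w <- if (weighted) atlas$region_weights[regions] else rep(1, length(regions))
    as.numeric(sub %*% w) / sum(w)
  }
  tmp <- wm(atlas$meta_roi_membership$temporal)
  mtl <- wm(atlas$meta_roi_membership$mtl, weighted = FALSE)
  neo <- wm(atlas$meta_roi_membership$neo)
  data.frame(
    participant_id = cohort$meta$participant_id,
    temporal_suvr = tmp, mtl_suvr = mtl, neo_suvr = neo,
    temporal_pos = as.integer(tmp > cfg$temporal),
    mtl_pos = as.integer(mtl > cfg$mtl),
    neo_pos = as.integer(neo > cfg$neo),
    stringsAsFactors = FALSE
  )
}

#' Concordance between visual rating and meta-ROI statuses
#'
#' A scan is concordant when the visual rating agrees with all three meta-ROI
#' statuses, discordant otherwise. The discordance pattern lists the meta-ROIs
#' that disagree with the visual rating (empty for concordant scans).
#' Participants with a missing visual rating are excluded with a warning.
#'
#' @param cohort A `cohort_table` with a `visual_rating` column.
#' @param meta Meta-ROI table from [meta_roi_table()].
#' @return data.frame with `participant_id`, `concordance`
#'   ("concordant"/"discordant") and `pattern`.
#' @export
label_concordance <- function(cohort, meta = meta_roi_table(cohort)) {
  if (!"visual_rating" %in% names(cohort$meta)) {
    stop_thetapet("thetapet_format_error", "cohort lacks visual_rating")
  }
  m <- merge(cohort$meta[, c("participant_id", "visual_rating")], meta,
             by = "participant_id", sort = FALSE)
  drop <- is.na(m$visual_rating)
  if (any(drop)) {
    warning(sprintf("excluding %d participant(s) with missing visual rating",
                    sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  dis <- cbind(temporal = m$temporal_pos != m$visual_rating,
               mtl = m$mtl_pos != m$visual_rating,
               neo = m$neo_pos != m$visual_rating)
  pattern <- apply(dis, 1L, function(r) paste(colnames(dis)[r], collapse = "+"))
  data.frame(
    participant_id = m$participant_id,
    concordance = ifelse(rowSums(dis) == 0L, "concordant", "discordant"),
    pattern = pattern,
    stringsAsFactors = FALSE
  )
}
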