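#' Cohort container: metadata plus regional SUVR panels
#'
#' A `cohort_table` pairs one row of participant metadata with one 41-region
#' SUVR panel per participant. The SUVR matrix columns always follow the atlas
#' region order — classifier feature order is read from the atlas, never from
#' file column order.
#'
#' @param meta data.frame with at least `participant_id`; recognised clinical
#'   columns are `visual_rating` (0/1), `diagnosis` (CU/MCI/AD/DLB), `mmse`
#'   (0-30), `cdr_sb` (0-18), `age`, `sex`, `amyloid_status`, `apoe4`.
#'   Missing clinical values are `NA` and are never imputed.
#' @param suvr Numeric matrix, participants x regions, with region column
#'   names; all values finite and > 0.
#' @param atlas [atlas_config()] object.
#' @param provenance Free-text label recorded with the cohort.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(meta, suvr, atlas = atlas_config(),
                         provenance = "unspecified") {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(meta)) {
    stop_thetapet("thetapet_format_error", "metadata lacks column 'participant_id'")
  }
  meta$participant_id <- as.character(meta$participant_id)
  if (anyDuplicated(meta$participant_id)) {
    dup <- meta$participant_id[duplicated(meta$participant_id)][1L]
    stop_thetapet("thetapet_integrity_error",
                  "duplicated participant_id: '%s'", dup)
  }
  suvr <- as.matrix(suvr)
  if (nrow(suvr) != nrow(meta)) {
    stop_thetapet("thetapet_integrity_error",
                  "metadata rows (%d) and SUVR rows (%d) differ",
                  nrow(meta), nrow(suvr))
  }
  missing_cols <- setdiff(atlas$region_names, colnames(suvr))
  if (length(missing_cols)) {
    stop_thetapet("thetapet_format_error",
                  "missing required region column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  suvr <- suvr[, atlas$region_names, drop = FALSE]
  storage.mode(suvr) <- "double"
  bad <- which(!is.finite(suvr) | suvr <= 0, arr.ind = TRUE)
  if (nrow(meta) > 0L && nrow(bad)) {
    stop_thetapet("thetapet_validation_error",
                  "non-positive or non-finite SUVR for participant '%s', region '%s'",
                  meta$participant_id[bad[1L, 1L]], colnames(suvr)[bad[1L, 2L]])
  }
  if ("mmse" %in% names(meta)) {
    v <- meta$mmse
    if (any(!is.na(v) & (v < 0 | v > 30))) {
      stop_thetapet("thetapet_validation_error", "mmse outside [0, 30]")
    }
  }
  if ("cdr_sb" %in% names(meta)) {
    v <- meta$cdr_sb
    if (any(!is.na(v) & (v < 0 | v > 18))) {
      stop_thetapet("thetapet_validation_error", "cdr_sb outside [0, 18]")
    }
  }
  rownames(suvr) <- meta$participant_id
  structure(
    list(meta = meta, suvr = suvr, atlas = atlas, provenance = provenance),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants x %d regions (%s)\n",
              nrow(x$suvr), ncol(x$suvr), x$provenance))
  if ("visual_rating" %in% names(x$meta)) {
    pos <- sum(x$meta$visual_rating == 1, na.rm = TRUE)
    cat(sprintf("  visually tau-positive: %d (%.0f%%)\n",
                pos, 100 * pos / max(1L, nrow(x$meta))))
  }
  invisible(x)
}

#' Number of participants in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
n_participants <- function(cohort) nrow(cohort$suvr)

#' Extract one participant's SUVR panel
#'
#' @param cohort A `cohort_table`.
#' @param participant_id Participant identifier.
#' @return Named numeric vector of SUVR values in atlas region order.
#' @export
suvr_panel <- function(cohort, participant_id) {
  i <- match(as.character(participant_id), cohort$meta$participant_id)
  if (is.na(i)) {
    stop_thetapet("thetapet_integrity_error",
                  "unknown participant_id: '%s'", participant_id)
  }
  cohort$suvr[i, ]
}

read_delim_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    stop_thetapet("thetapet_format_error", "file not found: %s", path)
  }
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA)
}

#' Load a cohort from delimited text files
#'
#' Reads a regional SUVR table (`participant_id` plus one column per atlas
#' region) and a participant metadata table, joins them on `participant_id`,
#' and validates the result. Participants present in only one of the two files
#' are reported via a warning and dropped. SUVR columns must be numeric: no
#' silent coercion is performed.
#'
#' @param suvr_path,metadata_path Paths to delimited text files with a header
#'   row. Comma-delimited by default.
#' @param atlas [atlas_config()] giving region order and meta-ROI membership.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param provenance Label stored on the returned cohort.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(suvr_path, metadata_path, atlas = atlas_config(),
                        delim = ",", provenance = NULL) {
  suvr_df <- read_delim_table(suvr_path, delim)
  meta_df <- read_delim_table(metadata_path, delim)
  for (df_name in c("suvr", "metadata")) {
    df <- if (df_name == "suvr") suvr_df else meta_df
    if (!"participant_id" %in% names(df)) {
      stop_thetapet("thetapet_format_error",
                    "%s file lacks column 'participant_id'", df_name)
    }
  }
  missing_cols <- setdiff(atlas$region_names, names(suvr_df))
  if (length(missing_cols)) {
    stop_thetapet("thetapet_format_error",
                  "missing required region column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  suvr_df$participant_id <- as.character(suvr_df$participant_id)
  meta_df$participant_id <- as.character(meta_df$participant_id)
  for (ids in list(suvr_df$participant_id, meta_df$participant_id)) {
    if (anyDuplicated(ids)) {
      stop_thetapet("thetapet_integrity_error",
                    "duplicated participant_id: '%s'",
                    ids[duplicated(ids)][1L])
    }
  }
  for (rg in atlas$region_names) {
    if (!is.numeric(suvr_df[[rg]])) {
      stop_thetapet("thetapet_format_error",
                    "region column '%s' is not numeric", rg)
    }
  }
  common <- intersect(suvr_df$participant_id, meta_df$participant_id)
  orphans <- length(setdiff(suvr_df$participant_id, common)) +
    length(setdiff(meta_df$participant_id, common))
  if (orphans > 0L) {
    warning(sprintf("dropping %d participant(s) present in only one file", orphans))
  }
  suvr_df <- suvr_df[match(common, suvr_df$participant_id), , drop = FALSE]
  meta_df <- meta_df[match(common, meta_df$participant_id), , drop = FALSE]
  suvr <- as.matrix(suvr_df[, atlas$region_names, drop = FALSE])
  cohort_table(meta_df, suvr, atlas = atlas,
               provenance = provenance %||% basename(suvr_path))
}

#' Write a cohort to a pair of delimited text files
#'
#' Inverse of [load_cohort()]: writes the SUVR table and the metadata table.
#' Missing clinical values are written as empty cells.
#'
#' @param cohort A `cohort_table`.
#' @param suvr_path,metadata_path Output file paths.
#' @param delim Field delimiter.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, suvr_path, metadata_path, delim = ",") {
  suvr_df <- data.frame(participant_id = cohort$meta$participant_id,
                        cohort$suvr, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(suvr_df, suvr_path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  utils::write.table(cohort$meta, metadata_path, sep = delim,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(c(suvr_path, metadata_path))
}

#' Write per-participant scores next to meta-ROI and model outputs
#'
#' Produces the flat score table of a run: identifiers, the three meta-ROI
#' SUVRs and statuses, predicted probability and status, THETA, and one
#' regional THETA column per atlas region. Only columns present in `results`
#' are written beyond `participant_id`; an empty results table yields a
#' header-only file.
#'
#' @param cohort A `cohort_table`.
#' @param results data.frame keyed by `participant_id` (a subset of the
#'   cohort's participants) with any of the score columns described above.
#' @param out_path Output file path.
#' @param delim Field delimiter.
#' @return Invisibly, `out_path`.
#' @export
write_scores <- function(cohort, results, out_path, delim = ",") {
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(results)) {
    stop_thetapet("thetapet_format_error", "results lack 'participant_id'")
  }
  results$participant_id <- as.character(results$participant_id)
  unknown <- setdiff(results$participant_id, cohort$meta$participant_id)
  if (length(unknown)) {
    stop_thetapet("thetapet_integrity_error",
                  "results contain unknown participant_id: '%s'", unknown[1L])
  }
  utils::write.table(results, out_path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(out_path)
}

#' Read a score table written by [write_scores()]
#' @param path File path.
#' @param delim Field delimiter.
#' @return data.frame.
#' @export
read_scores <- function(path, delim = ",") {
  read_delim_table(path, delim)
}
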