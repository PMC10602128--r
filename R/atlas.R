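#' Canonical 41-region atlas for tau-PET SUVR panels
#'
#' The package works on 41 regional SUVR values per participant, each the mean
#' of the left and right hemisphere values, referenced to the cerebellar crus.
#' The shipped region list uses lowercase tokens covering the cortical
#' parcellation plus the medial-temporal and subcortical structures that enter
#' the meta-ROIs. Users of a different atlas can rename regions through
#' [atlas_config()]; the meta-ROI membership sets must then be mapped
#' accordingly.
#'
#' @return Character vector of 41 region names.
#' @export
tau_atlas_regions <- function() {
  c(
    "bankssts", "caudal_anterior_cingulate", "caudal_middle_frontal", "cuneus",
    "entorhinal", "frontal_pole", "fusiform", "inferior_parietal",
    "inferior_temporal", "insula", "isthmus_cingulate", "lateral_occipital",
    "lateral_orbitofrontal", "lingual", "medial_orbitofrontal",
    "middle_temporal", "paracentral", "parahippocampal", "pars_opercularis",
    "pars_orbitalis", "pars_triangularis", "pericalcarine", "postcentral",
    "posterior_cingulate", "precentral", "precuneus",
    "rostral_anterior_cingulate", "rostral_middle_frontal", "superior_frontal",
    "superior_parietal", "superior_temporal", "supramarginal", "temporal_pole",
    "transverse_temporal", "amygdala", "hippocampus", "thalamus", "caudate",
    "putamen", "pallidum", "accumbens"
  )
}

#' Atlas configuration
#'
#' Defines the region list (classifier feature order), per-region weights used
#' in voxel-weighted meta-ROI averages (stand-ins for voxel counts; equal by
#' default), and the meta-ROI membership sets:
#' \describe{
#'   \item{temporal}{entorhinal, amygdala, parahippocampal, fusiform,
#'     inferior temporal, middle temporal (voxel-weighted average)}
#'   \item{mtl}{entorhinal + amygdala (unweighted average)}
#'   \item{neo}{middle temporal + inferior temporal (voxel-weighted average)}
#' }
#'
#' @param region_names Ordered character vector of region names.
#' @param region_weights Named positive numeric vector, one entry per region.
#'   Defaults to equal weights.
#' @param meta_roi_membership Named list of character vectors giving the member
#'   regions of each meta-ROI; must contain `temporal`, `mtl` and `neo`.
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(region_names = tau_atlas_regions(),
                         region_weights = NULL,
                         meta_roi_membership = NULL) {
  region_names <- as.character(region_names)
  if (anyDuplicated(region_names)) {
    stop_thetapet("thetapet_config_error", "atlas region names must be unique")
  }
  if (is.null(region_weights)) {
    region_weights <- stats::setNames(rep(1, length(region_names)), region_names)
  }
  if (is.null(names(region_weights)) ||
      !setequal(names(region_weights), region_names)) {
    stop_thetapet("thetapet_config_error",
                  "region_weights must be named by the atlas regions")
  }
  if (any(!is.finite(region_weights)) || any(region_weights <= 0)) {
    stop_thetapet("thetapet_config_error", "all region weights must be > 0")
  }
  if (is.null(meta_roi_membership)) {
    meta_roi_membership <- list(
      temporal = c("entorhinal", "amygdala", "parahippocampal", "fusiform",
                   "inferior_temporal", "middle_temporal"),
      mtl = c("entorhinal", "amygdala"),
      neo = c("middle_temporal", "inferior_temporal")
    )
  }
  for (nm in c("temporal", "mtl", "neo")) {
    members <- meta_roi_membership[[nm]]
    if (is.null(members) || length(members) == 0L) {
      stop_thetapet("thetapet_config_error",
                    "meta_roi_membership must define '%s'", nm)
    }
    missing <- setdiff(members, region_names)
    if (length(missing)) {
      stop_thetapet("thetapet_config_error",
                    "meta-ROI '%s' references unknown region(s): %s",
                    nm, paste(missing, collapse = ", "))
    }
  }
  structure(
    list(region_names = region_names,
         region_weights = region_weights[region_names],
         meta_roi_membership = meta_roi_membership),
    class = "atlas_config"
  )
}

#' @export
print.atlas_config <- function(x, ...) {
  cat(sprintf("<atlas_config> %d regions\n", length(x$region_names)))
  for (nm in names(x$meta_roi_membership)) {
    cat(sprintf("  %s meta-ROI: %s\n", nm,
                paste(x$meta_roi_membership[[nm]], collapse = ", ")))
  }
  invisible(x)
}
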