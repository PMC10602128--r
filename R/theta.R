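#' THETA configuration
#'
#' Controls the percentile band of Shapley values whose SUVR-weighted
#' contributions enter the second THETA component. Default band: 1st to 99th
#' percentile, linear-interpolation quantiles. Scope `"per_scan"` (default)
#' computes the band over a scan's own regional attributions, which keeps the
#' score computable for a single participant; `"cohort_per_region"` computes
#' per-region bands across the cohort.
#'
#' @param lower_percentile,upper_percentile Band bounds in [0, 100],
#'   `lower < upper`.
#' @param percentile_scope `"per_scan"` or `"cohort_per_region"`.
#' @return Object of class `theta_config`.
#' @export
theta_config <- function(lower_percentile = 1, upper_percentile = 99,
                         percentile_scope = c("per_scan", "cohort_per_region")) {
  if (!(lower_percentile >= 0 && lower_percentile < upper_percentile &&
        upper_percentile <= 100)) {
    stop_thetapet("thetapet_config_error",
                  "need 0 <= lower < upper <= 100")
  }
  structure(
    list(lower_percentile = lower_percentile,
         upper_percentile = upper_percentile,
         percentile_scope = match.arg(percentile_scope),
         interpolation = "linear"),
    class = "theta_config"
  )
}

#' Percentile inclusion mask over a vector of Shapley values
#'
#' Computes the `[lower, upper]` percentile bounds of `phi_row` (linear
#' interpolation between order statistics) and includes region `i` iff
#' `lower_bound <= phi_i <= upper_bound`. When all values are equal the
#' bounds collapse onto the common value and every region is included.
#'
#' @param phi_row Numeric vector of regional attributions (length >= 2).
#' @param cfg [theta_config()].
#' @return Logical inclusion vector.
#' @export
percentile_mask <- function(phi_row, cfg = theta_config()) {
  if (length(phi_row) < 2L) {
    stop_thetapet("thetapet_validation_error", "need at least 2 regions")
  }
  b <- stats::quantile(phi_row,
                       c(cfg$lower_percentile, cfg$upper_percentile) / 100,
                       type = 7, names = FALSE)
  phi_row >= b[1L] & phi_row <= b[2L]
}

#' THETA score for one participant
#'
#' \deqn{\Theta = \sum_{i=1}^m \phi_i + \sum_{i=1}^m \hat\phi_i x_i}
#' where \eqn{\phi_i} are the regional Shapley values, \eqn{x_i} the regional
#' SUVRs, and \eqn{\hat\phi_i = \phi_i} when region `i` falls inside the
#' percentile band (else 0). The first sum always runs over all regions. The
#' per-region decomposition \eqn{\theta_i = \phi_i + \hat\phi_i x_i} sums to
#' \eqn{\Theta} exactly.
#'
#' @param phi_row Named regional attribution vector.
#' @param panel Named regional SUVR vector in the same order.
#' @param cfg [theta_config()].
#' @param mask Optional precomputed inclusion mask (used by [batch_theta()]
#'   for the cohort-level scope); defaults to [percentile_mask()] of
#'   `phi_row`.
#' @return Object of class `theta_result`: `theta`, `regional_theta`,
#'   `phi_sum`, `weighted_sum`, `included_mask`.
#' @export
theta <- function(phi_row, panel, cfg = theta_config(), mask = NULL) {
  if (length(phi_row) != length(panel)) {
    stop_thetapet("thetapet_integrity_error",
                  "phi (%d) and panel (%d) lengths differ",
                  length(phi_row), length(panel))
  }
  if (!is.null(names(phi_row)) && !is.null(names(panel)) &&
      !identical(names(phi_row), names(panel))) {
    stop_thetapet("thetapet_integrity_error",
                  "phi and panel region order differ")
  }
  if (is.null(mask)) mask <- percentile_mask(phi_row, cfg)
  phi_hat <- ifelse(mask, phi_row, 0)
  regional <- phi_row + phi_hat * panel
  structure(
    list(theta = sum(phi_row) + sum(phi_hat * panel),
         regional_theta = regional,
         phi_sum = sum(phi_row),
         weighted_sum = sum(phi_hat * panel),
         included_mask = mask),
    class = "theta_result"
  )
}

#' @export
print.theta_result <- function(x, ...) {
  cat(sprintf("<theta_result> theta = %.4f (phi_sum = %.4f, weighted_sum = %.4f; %d/%d regions in band)\n",
              x$theta, x$phi_sum, x$weighted_sum,
              sum(x$included_mask), length(x$included_mask)))
  invisible(x)
}

#' THETA scores for a whole cohort
#'
#' @param matrix `shap_matrix` aligned with `cohort`.
#' @param cohort A `cohort_table`.
#' @param cfg [theta_config()].
#' @return data.frame: `participant_id`, `theta`, `phi_sum`, `weighted_sum`,
#'   `n_included`, then one `theta_<region>` column per region.
#' @export
batch_theta <- function(matrix, cohort, cfg = theta_config()) {
  phi <- matrix$values
  X <- cohort$suvr
  if (nrow(phi) != nrow(X)) {
    stop_thetapet("thetapet_integrity_error",
                  "attribution rows (%d) and cohort rows (%d) differ",
                  nrow(phi), nrow(X))
  }
  if (cfg$percentile_scope == "cohort_per_region") {
    lb <- apply(phi, 2L, stats::quantile, cfg$lower_percentile / 100, type = 7)
    ub <- apply(phi, 2L, stats::quantile, cfg$upper_percentile / 100, type = 7)
    masks <- sweep(phi, 2L, lb, ">=") & sweep(phi, 2L, ub, "<=")
  } else {
    masks <- t(apply(phi, 1L, percentile_mask, cfg = cfg))
  }
  phi_hat <- phi * masks
  regional <- phi + phi_hat * X
  out <- data.frame(
    participant_id = cohort$meta$participant_id,
    theta = rowSums(regional),
    phi_sum = rowSums(phi),
    weighted_sum = rowSums(phi_hat * X),
    n_included = rowSums(masks),
    stringsAsFactors = FALSE
  )
  colnames(regional) <- paste0("theta_", colnames(X))
  cbind(out, as.data.frame(regional, optional = TRUE))
}

#' Regional THETA ranking for a subgroup
#'
#' Ranks regions by the median of their per-participant regional THETA
#' contributions within a subgroup (ascending order, so the strongest
#' contributors appear last).
#'
#' @param theta_table Output of [batch_theta()].
#' @param participant_ids Subgroup; defaults to all rows.
#' @return data.frame with `region` and `median_theta`, ascending.
#' @export
regional_theta_ranking <- function(theta_table, participant_ids = NULL) {
  tt <- theta_table
  if (!is.null(participant_ids)) {
    tt <- tt[tt$participant_id %in% participant_ids, , drop = FALSE]
  }
  cols <- grep("^theta_", names(tt), value = TRUE)
  med <- vapply(tt[cols], stats::median, numeric(1))
  out <- data.frame(region = sub("^theta_", "", cols), median_theta = med,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$median_theta), , drop = FALSE]
}
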