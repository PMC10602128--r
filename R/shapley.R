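# Shapley attribution of the positive-class probability to individual regions.
#
# The value function is the interventional expectation: v(S) is the mean model
# output over a background set whose rows have the regions in S replaced by the
# explained panel's values. exact_shapley() enumerates all coalitions (m <= 15);
# sampled_shapley() estimates the same quantity by permutation sampling with
# antithetic pairs, then restores exact additivity by spreading the residual
# evenly over the regions.

as_predict_fun <- function(model) {
  if (inherits(model, "tau_classifier")) {
    function(X) predict_proba(model, X)
  } else if (is.function(model)) {
    function(X) as.numeric(model(X))
  } else {
    stop_thetapet("thetapet_config_error",
                  "model must be a tau_classifier or a prediction function")
  }
}

as_background_matrix <- function(background, region_names) {
  X <- if (inherits(background, "cohort_table")) background$suvr
       else as.matrix(background)
  if (nrow(X) == 0L) {
    stop_thetapet("thetapet_config_error", "background set is empty")
  }
  if (!is.null(colnames(X)) && !is.null(region_names)) {
    missing <- setdiff(region_names, colnames(X))
    if (length(missing)) {
      stop_thetapet("thetapet_config_error",
                    "background lacks region(s): %s",
                    paste(missing, collapse = ", "))
    }
    X <- X[, region_names, drop = FALSE]
  }
  X
}

#' Draw a seeded background subsample from a cohort
#'
#' @param cohort A `cohort_table` (typically the training set).
#' @param n_background Number of reference rows (default 100).
#' @param seed Integer seed.
#' @return SUVR matrix of background rows.
#' @export
shap_background <- function(cohort, n_background = 100L, seed = 1L) {
  n <- nrow(cohort$suvr)
  idx <- if (n <= n_background) seq_len(n) else
    with_seed(derive_seed(seed, 77L), sample.int(n, n_background))
  cohort$suvr[idx, , drop = FALSE]
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Computes \eqn{\phi_i = \sum_{S \subseteq N \setminus \{i\}}
#' \frac{|S|!\,(m-|S|-1)!}{m!}\,[v(S \cup \{i\}) - v(S)]} over all
#' \eqn{2^m} coalitions. Feasible for `m <= 15` regions; larger panels must
#' use [sampled_shapley()]. Additivity
#' `base_value + sum(phi) = f(panel)` holds to numerical precision.
#'
#' @param model A `tau_classifier` or a function mapping an SUVR matrix to
#'   probabilities.
#' @param panel Named numeric SUVR vector for the participant being explained.
#' @param background Background rows (matrix or `cohort_table`).
#' @return List with `phi` (named attribution vector) and `base_value`
#'   (mean model output over the background).
#' @export
exact_shapley <- function(model, panel, background) {
  f <- as_predict_fun(model)
  x <- if (is.matrix(panel)) panel[1L, ] else panel
  m <- length(x)
  if (m > 15L) {
    stop_thetapet("thetapet_feasibility_error",
                  "exact enumeration infeasible for m = %d (> 15); use sampled_shapley", m)
  }
  bg <- as_background_matrix(background, names(x))
  B <- nrow(bg)
  n_masks <- bitwShiftL(1L, m)
  bits <- matrix(FALSE, n_masks, m)
  for (i in seq_len(m)) {
    bits[, i] <- bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  sizes <- rowSums(bits)
  # v(S) for every coalition, evaluated in chunks of masks
  v <- numeric(n_masks)
  chunk <- max(1L, floor(200000 / B))
  for (start in seq(1L, n_masks, by = chunk)) {
    masks <- start:min(n_masks, start + chunk - 1L)
    Z <- bg[rep(seq_len(B), times = length(masks)), , drop = FALSE]
    for (jj in seq_along(masks)) {
      on <- which(bits[masks[jj], ])
      if (length(on)) {
        rows <- ((jj - 1L) * B + 1L):(jj * B)
        Z[rows, on] <- matrix(x[on], B, length(on), byrow = TRUE)
      }
    }
    pv <- f(Z)
    v[masks] <- colMeans(matrix(pv, B, length(masks)))
  }
  w <- factorial(0:(m - 1L)) * factorial(m - 1L - (0:(m - 1L))) / factorial(m)
  phi <- stats::setNames(numeric(m), names(x))
  mask_id <- seq_len(n_masks) - 1L
  for (i in seq_len(m)) {
    without <- which(!bits[, i])
    s <- sizes[without]
    with_i <- mask_id[without] + bitwShiftL(1L, i - 1L) + 1L
    phi[i] <- sum(w[s + 1L] * (v[with_i] - v[without]))
  }
  list(phi = phi, base_value = v[1L])
}

make_permutations <- function(m, n_permutations, seed) {
  n_pairs <- ceiling(n_permutations / 2)
  perms <- with_seed(derive_seed(seed, 13L), {
    lapply(seq_len(n_pairs), function(i) sample.int(m))
  })
  out <- vector("list", 2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    out[[2L * i - 1L]] <- perms[[i]]
    out[[2L * i]] <- rev(perms[[i]])       # antithetic partner
  }
  out[seq_len(n_permutations)]
}

# Core permutation-walk estimator, vectorised over participants. X is a
# P x m matrix of panels sharing one permutation stream.
sampled_shapley_core <- function(f, X, bg, n_permutations, seed) {
  P <- nrow(X)
  m <- ncol(X)
  B <- nrow(bg)
  base <- mean(f(bg))
  perms <- make_permutations(m, n_permutations, seed)
  phi <- matrix(0, P, m, dimnames = list(rownames(X), colnames(X)))
  # chunk participants so one predict call stays below ~200k rows
  chunk_p <- max(1L, floor(200000 / (m * B)))
  for (start in seq(1L, P, by = chunk_p)) {
    pid <- start:min(P, start + chunk_p - 1L)
    Pc <- length(pid)
    bg_t <- bg[rep(seq_len(B), times = Pc), , drop = FALSE]
    xrep <- X[rep(pid, each = B), , drop = FALSE]
    for (perm in perms) {
      big <- matrix(0, m * Pc * B, m)
      Z <- bg_t
      for (j in seq_len(m)) {
        fcol <- perm[j]
        Z[, fcol] <- xrep[, fcol]
        big[((j - 1L) * Pc * B + 1L):(j * Pc * B), ] <- Z
      }
      colnames(big) <- colnames(X)
      vbar <- matrix(colMeans(matrix(f(big), B, Pc * m)), Pc, m)
      marg <- cbind(vbar[, 1L] - base,
                    vbar[, -1L, drop = FALSE] - vbar[, -m, drop = FALSE])
      phi[pid, perm] <- phi[pid, perm] + marg
    }
  }
  phi <- phi / length(perms)
  # additive renormalization: spread the residual evenly so that
  # base + sum(phi) equals the prediction exactly
  pred <- f(X)
  resid <- pred - base - rowSums(phi)
  phi <- phi + resid / m
  list(phi = phi, base_value = base, pred = pred)
}

#' Permutation-sampling Shapley attribution
#'
#' Monte-Carlo estimate of the same attribution as [exact_shapley()]:
#' random feature orderings are walked one region at a time, accumulating
#' marginal contributions against the background expectation. Permutations
#' are drawn in antithetic pairs (each ordering together with its reverse) to
#' reduce variance. After estimation the residual
#' `f(panel) - base_value - sum(phi)` is spread evenly across regions so that
#' additivity holds exactly. Deterministic given `seed`.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of permutations (>= 50).
#' @param seed Integer seed.
#' @return List with `phi` and `base_value`.
#' @export
sampled_shapley <- function(model, panel, background, n_permutations = 200L,
                            seed = 1L) {
  if (n_permutations < 50L) {
    stop_thetapet("thetapet_config_error", "n_permutations must be >= 50")
  }
  f <- as_predict_fun(model)
  x <- if (is.matrix(panel)) panel[1L, ] else panel
  bg <- as_background_matrix(background, names(x))
  X <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  res <- sampled_shapley_core(f, X, bg, n_permutations, seed)
  list(phi = res$phi[1L, ], base_value = res$base_value)
}

#' Shapley attribution matrix for a cohort
#'
#' Stacks per-participant attribution rows into a participants x regions
#' matrix. The sampled method shares one permutation stream across all
#' participants, which lets the background walks be evaluated in large
#' batches.
#'
#' @param model A `tau_classifier` or prediction function.
#' @param cohort A `cohort_table` of participants to explain.
#' @param background Background rows (matrix or `cohort_table`); defaults to a
#'   seeded 100-row subsample of `cohort`.
#' @param method `"sampled"` (default; any m) or `"exact"` (m <= 15).
#' @param n_permutations Permutations for the sampled method.
#' @param seed Integer seed.
#' @return Object of class `shap_matrix` with `values` (participants x
#'   regions), `base_value`, `pred` (the explained probabilities) and
#'   `background_spec`.
#' @export
attribution_matrix <- function(model, cohort, background = NULL,
                               method = c("sampled", "exact"),
                               n_permutations = 200L, seed = 1L) {
  method <- match.arg(method)
  f <- as_predict_fun(model)
  X <- cohort$suvr
  if (is.null(background)) background <- shap_background(cohort, seed = seed)
  bg <- as_background_matrix(background, colnames(X))
  if (method == "exact") {
    rows <- lapply(seq_len(nrow(X)), function(i) {
      exact_shapley(model, X[i, ], bg)
    })
    values <- do.call(rbind, lapply(rows, function(r) r$phi))
    rownames(values) <- rownames(X)
    base <- rows[[1L]]$base_value
    pred <- f(X)
  } else {
    res <- sampled_shapley_core(f, X, bg, n_permutations, seed)
    values <- res$phi
    base <- res$base_value
    pred <- res$pred
  }
  structure(
    list(values = values, base_value = base, pred = pred,
         participant_id = cohort$meta$participant_id,
         background_spec = list(n_background = nrow(bg), method = method,
                                n_permutations =
                                  if (method == "sampled") n_permutations else NA_integer_,
                                seed = seed)),
    class = "shap_matrix"
  )
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d participants x %d regions (%s, base = %.4f)\n",
              nrow(x$values), ncol(x$values), x$background_spec$method,
              x$base_value))
  invisible(x)
}

#' Check Shapley additivity for every participant
#'
#' Reports the per-participant residual
#' `|base_value + sum(phi) - predicted probability|` and flags rows above
#' tolerance.
#'
#' @param matrix A `shap_matrix`.
#' @param model The model the matrix explains.
#' @param cohort The cohort the matrix rows align with.
#' @param tolerance Flagging threshold.
#' @return data.frame with `participant_id`, `residual`, `flagged`.
#' @export
check_additivity <- function(matrix, model, cohort, tolerance = 1e-9) {
  f <- as_predict_fun(model)
  pred <- f(cohort$suvr)
  resid <- abs(matrix$base_value + rowSums(matrix$values) - pred)
  data.frame(participant_id = cohort$meta$participant_id,
             residual = resid, flagged = resid > tolerance,
             stringsAsFactors = FALSE)
}
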