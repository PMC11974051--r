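#' Shift a residual matrix to be non-negative
#'
#' Adds `|min|` to every entry when the minimum is negative (shift 0
#' otherwise), the minimal translation making the matrix factorizable by
#' NMF.
#'
#' @param residual A `residual_matrix` or plain numeric matrix.
#' @return List with `values` (matrix, min >= 0) and `shift_value`.
#' @export
shift_nonnegative <- function(residual) {
  values <- if (inherits(residual, "residual_matrix")) residual$values
            else residual
  stopifnot(is.matrix(values))
  mn <- min(values)
  shift <- if (mn < 0) -mn else 0
  list(values = values + shift, shift_value = shift)
}

#' Factorize a residual matrix with NMF
#'
#' Shifts the residual to non-negative, then factorizes it with
#' NNDSVD-initialised NMF using `k = n_missing + 1` factors: one candidate
#' factor per suspected missing cell type plus one to absorb other sources
#' of variability.
#'
#' @param residual A `residual_matrix` (or plain samples x genes matrix).
#' @param n_missing Number of suspected missing cell types (>= 0).
#' @param max_iter NMF iteration cap (default 10000).
#' @param tol Convergence tolerance passed to [nmf_factorize()].
#' @return An object of class `factorization_result` with `sample_weights`
#'   (samples x k), `gene_loadings` (k x genes), `k`, `shift_value`,
#'   `n_iterations_used`, `converged`, `reconstruction_error` and `solver`
#'   metadata.
#' @export
factorize_residual <- function(residual, n_missing, max_iter = 10000L,
                               tol = 1e-5) {
  stopifnot(n_missing >= 0)
  shifted <- shift_nonnegative(residual)
  a <- shifted$values
  k <- as.integer(n_missing) + 1L
  if (k > min(dim(a))) {
    stop("k = n_missing + 1 = ", k, " exceeds min(samples, genes) = ",
         min(dim(a)))
  }
  fit <- nmf_factorize(a, k, max_iter = max_iter, tol = tol)
  w <- fit$w
  h <- fit$h
  rownames(w) <- rownames(a)
  colnames(w) <- paste0("factor", seq_len(k))
  rownames(h) <- colnames(w)
  colnames(h) <- colnames(a)
  structure(
    list(sample_weights = w,
         gene_loadings = h,
         k = k,
         shift_value = shifted$shift_value,
         n_iterations_used = fit$n_iterations_used,
         converged = fit$converged,
         reconstruction_error = fit$reconstruction_error,
         solver = "multiplicative-update (Frobenius), NNDSVD init"),
    class = "factorization_result"
  )
}

#' Scale factor sample-weights to the proportion scale
#'
#' Per factor (column), applies `(w - min) / (max - min)` so weights live on
#' `[0, 1]` like proportions; a constant factor maps to zeros.
#'
#' @param sample_weights samples x k non-negative matrix, or a
#'   `factorization_result`.
#' @return samples x k matrix with each non-constant column spanning `[0, 1]`.
#' @export
scale_factor_weights <- function(sample_weights) {
  if (inherits(sample_weights, "factorization_result")) {
    sample_weights <- sample_weights$sample_weights
  }
  stopifnot(is.matrix(sample_weights), all(sample_weights >= 0))
  apply(sample_weights, 2, function(w) {
    rng <- range(w)
    if (rng[2] == rng[1]) return(w * 0)
    (w - rng[1]) / (rng[2] - rng[1])
  })
}

#' Match NMF factors to missing cell-type proportions
#'
#' Computes the full factors x missing-types grid of Pearson correlations
#' (and, for random proportions, RMSE) between scaled factor weights and
#' each missing type's true proportions, and assigns each missing type its
#' best-matching factor (highest r; ties by lower RMSE, then lower factor
#' index). RMSE is omitted for realistic proportions, whose narrow range
#' makes it uninformative.
#'
#' @param scaled_weights Output of [scale_factor_weights()] (samples x k).
#' @param missing_truth samples x missing-types matrix of true proportions
#'   of the removed types.
#' @param proportions_mode `"random"` or `"realistic"`.
#' @return An object of class `recovery_report` with `r_grid`, `rmse_grid`
#'   (or `NULL`), `best_match` data frame and `proportions_mode`.
#' @export
match_factors <- function(scaled_weights, missing_truth,
                          proportions_mode = c("random", "realistic")) {
  proportions_mode <- match.arg(proportions_mode)
  stopifnot(is.matrix(scaled_weights), is.matrix(missing_truth),
            nrow(scaled_weights) == nrow(missing_truth))
  if (!is.null(rownames(scaled_weights)) && !is.null(rownames(missing_truth))) {
    if (!setequal(rownames(scaled_weights), rownames(missing_truth))) {
      stop("sample id mismatch between factors and truth")
    }
    missing_truth <- missing_truth[rownames(scaled_weights), , drop = FALSE]
  }
  k <- ncol(scaled_weights)
  m <- ncol(missing_truth)
  types <- colnames(missing_truth) %||% paste0("missing", seq_len(m))
  r_grid <- matrix(NA_real_, k, m,
                   dimnames = list(colnames(scaled_weights) %||%
                                     paste0("factor", seq_len(k)), types))
  rmse_grid <- r_grid
  for (j in seq_len(k)) {
    for (t in seq_len(m)) {
      w <- scaled_weights[, j]
      p <- missing_truth[, t]
      if (var(w) > 0 && var(p) > 0) r_grid[j, t] <- cor(w, p)
      rmse_grid[j, t] <- sqrt(mean((w - p)^2))
    }
  }
  best <- data.frame(missing_type = types, factor = NA_integer_,
                     r = NA_real_, rmse = NA_real_)
  for (t in seq_len(m)) {
    ok <- which(!is.na(r_grid[, t]))
    if (length(ok) == 0) next
    ord <- ok[order(-r_grid[ok, t], rmse_grid[ok, t], ok)]
    best$factor[t] <- ord[1]
    best$r[t] <- r_grid[ord[1], t]
    best$rmse[t] <- rmse_grid[ord[1], t]
  }
  if (proportions_mode == "realistic") {
    rmse_grid <- NULL
    best$rmse <- NULL
  }
  structure(
    list(r_grid = r_grid,
         rmse_grid = rmse_grid,
         best_match = best,
         proportions_mode = proportions_mode),
    class = "recovery_report"
  )
}

#' Select samples in which missing cell types are rare
#'
#' Restricts the evaluation to samples where missing types are minor
#' constituents: `mode = "any"` keeps samples where at least one missing
#' type is below the threshold, `mode = "all"` requires every missing type
#' to be below it.
#'
#' @param truth samples x types ground-truth proportion matrix.
#' @param missing_types Character vector of the removed types.
#' @param threshold Rarity cutoff on the true proportion (default 0.05).
#' @param mode `"any"` or `"all"`.
#' @return Integer vector of sample indices (possibly empty, with warning).
#' @export
subset_by_rarity <- function(truth, missing_types, threshold = 0.05,
                             mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  missing <- setdiff(missing_types, colnames(truth))
  if (length(missing) > 0) {
    stop("missing types not in truth: ", paste(missing, collapse = ", "))
  }
  sub <- truth[, missing_types, drop = FALSE] < threshold
  keep <- if (mode == "any") which(apply(sub, 1, any))
          else which(apply(sub, 1, all))
  if (length(keep) == 0) {
    warning("no samples satisfy the rarity criterion (threshold ",
            threshold, ", mode '", mode, "')")
  }
  keep
}
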