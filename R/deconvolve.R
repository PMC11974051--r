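#' Non-negative least squares deconvolution
#'
#' Per sample, solves `min || t(S) x - b ||_2` subject to `x >= 0` over the
#' marker genes, where `S` is the scaled signature and `b` the scaled bulk
#' vector. Raw coefficients are kept, and proportions are obtained by
#' dividing by their sum; a sample whose coefficients are all zero is
#' flagged and left as zeros.
#'
#' @param bulks_scaled samples x genes matrix in `[0, 1]`, or a scaled
#'   `pseudobulk_set`.
#' @param signature_scaled A `signature_matrix` with `scaled = TRUE`.
#' @param markers Optional [marker_gene_set()]; defaults to all shared genes.
#' @return An object of class `deconv_result` with fields `proportions`
#'   (samples x types, rows summing to 1 except flagged samples),
#'   `raw_coefficients`, `method_name`, `genes_used` and `zero_samples`.
#' @export
nnls_deconvolve <- function(bulks_scaled, signature_scaled, markers = NULL) {
  if (inherits(bulks_scaled, "pseudobulk_set")) {
    bulks_scaled <- bulks_scaled$expression
  }
  stopifnot(is.matrix(bulks_scaled),
            inherits(signature_scaled, "signature_matrix"))
  if (!signature_scaled$scaled) {
    stop("signature must be clip_and_minmax scaled before NNLS")
  }
  if (max(bulks_scaled) > 1 + 1e-8 || min(bulks_scaled) < 0) {
    stop("bulks must be scaled to [0, 1] before NNLS")
  }
  types <- signature_scaled$type_names
  if (length(types) < 2) stop("need at least 2 cell types in the reference")
  genes <- intersect(colnames(bulks_scaled), signature_scaled$gene_names)
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "marker_gene_set"))
    genes <- intersect(genes, markers$union)
  }
  if (length(genes) < 2) {
    stop("fewer than 2 genes shared between bulks, signature and markers")
  }
  design <- t(signature_scaled$values[, genes, drop = FALSE])  # genes x types
  n <- nrow(bulks_scaled)
  raw <- matrix(0, n, length(types),
                dimnames = list(rownames(bulks_scaled), types))
  for (i in seq_len(n)) {
    b <- bulks_scaled[i, genes]
    if (all(b == 0)) next
    raw[i, ] <- pracma::lsqnonneg(design, b)$x
  }
  sums <- rowSums(raw)
  zero <- sums == 0
  props <- raw
  props[!zero, ] <- raw[!zero, , drop = FALSE] / sums[!zero]
  structure(
    list(proportions = props,
         raw_coefficients = raw,
         method_name = "nnls",
         genes_used = genes,
         zero_samples = rownames(raw)[zero] %||% which(zero)),
    class = "deconv_result"
  )
}

#' Compare estimated proportions with the ground truth
#'
#' Pools all (sample, type) pairs over the truth's type set; types absent
#' from the estimate (e.g. removed from the reference) are evaluated as
#' estimated zero. Pearson r and RMSE are reported pooled and per type.
#'
#' @param estimated samples x types proportion matrix or a `deconv_result`.
#' @param truth samples x types ground-truth proportion matrix.
#' @return List with `pooled` (`r`, `rmse`, `n`) and `per_type` (data frame
#'   with one row per truth type).
#' @export
evaluate_proportions <- function(estimated, truth) {
  if (inherits(estimated, "deconv_result")) estimated <- estimated$proportions
  stopifnot(is.matrix(estimated), is.matrix(truth))
  if (nrow(estimated) != nrow(truth)) stop("sample count mismatch")
  if (!is.null(rownames(estimated)) && !is.null(rownames(truth))) {
    if (!setequal(rownames(estimated), rownames(truth))) {
      stop("sample id mismatch")
    }
    estimated <- estimated[rownames(truth), , drop = FALSE]
  }
  types <- colnames(truth)
  est_full <- matrix(0, nrow(truth), length(types),
                     dimnames = list(rownames(truth), types))
  shared <- intersect(types, colnames(estimated))
  est_full[, shared] <- estimated[, shared]
  r_or_na <- function(a, b) {
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }
  pooled <- list(
    r = r_or_na(as.vector(est_full), as.vector(truth)),
    rmse = sqrt(mean((est_full - truth)^2)),
    n = length(truth)
  )
  per_type <- data.frame(
    type = types,
    r = vapply(types, function(t) r_or_na(est_full[, t], truth[, t]), 1),
    rmse = vapply(types, function(t) sqrt(mean((est_full[, t] - truth[, t])^2)), 1),
    row.names = NULL
  )
  list(pooled = pooled, per_type = per_type)
}

#' Wrap externally produced proportions as a deconvolution result
#'
#' Adapter so proportion matrices computed by external deconvolution tools
#' can flow through the residual and recovery stages. Rows must be
#' non-negative; rows whose sum is within 1% of 1 are renormalised, anything
#' else is rejected.
#'
#' @param name Method name recorded on the result.
#' @param proportions samples x types matrix, or path to a CSV with sample
#'   ids in the first column.
#' @return A `deconv_result`.
#' @export
register_external_proportions <- function(name, proportions) {
  if (is.character(proportions) && length(proportions) == 1) {
    proportions <- as.matrix(read.csv(proportions, row.names = 1,
                                      check.names = FALSE))
  }
  stopifnot(is.matrix(proportions))
  if (any(is.na(proportions))) stop("proportions contain missing values")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  sums <- rowSums(proportions)
  bad <- abs(sums - 1) > 0.01
  if (any(bad)) {
    stop("row sums deviate from 1 by more than 1%: ",
         paste(utils::head(rownames(proportions)[bad] %||% which(bad), 5),
               collapse = ", "))
  }
  props <- proportions / sums
  structure(
    list(proportions = props,
         raw_coefficients = proportions,
         method_name = name,
         genes_used = character(0),
         zero_samples = character(0)),
    class = "deconv_result"
  )
}
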