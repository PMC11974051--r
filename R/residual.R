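#' Reconstruct bulk-like expression from proportions and the reference
#'
#' Computes `P %*% S` over the signature's genes. By default the raw
#' (unnormalised) NNLS coefficients are used: they carry the overall scale
#' of the fit, so the reconstruction lives on the same scale as the bulks
#' and the residual isolates genuinely unexplained expression. Externally
#' imported proportion matrices reconstruct with their own values.
#'
#' @param result A `deconv_result` (or a plain samples x types matrix).
#' @param signature_scaled A scaled `signature_matrix` whose types cover the
#'   result's types.
#' @param use `"raw"` (default) or `"normalized"` coefficients.
#' @return samples x genes bulk-like matrix.
#' @export
reconstruct_bulks <- function(result, signature_scaled,
                              use = c("raw", "normalized")) {
  use <- match.arg(use)
  if (inherits(result, "deconv_result")) {
    p <- if (use == "raw") result$raw_coefficients else result$proportions
    method <- result$method_name
  } else {
    p <- result
    method <- "unknown"
  }
  stopifnot(is.matrix(p), inherits(signature_scaled, "signature_matrix"))
  if (!signature_scaled$scaled) stop("signature must be scaled")
  types <- colnames(p)
  missing <- setdiff(types, signature_scaled$type_names)
  if (length(missing) > 0) {
    stop("types absent from the signature: ", paste(missing, collapse = ", "))
  }
  bl <- p %*% signature_scaled$values[types, , drop = FALSE]
  attr(bl, "method") <- method
  bl
}

#' Compute the deconvolution residual
#'
#' Elementwise difference between the scaled bulks and the bulk-like
#' reconstruction over the shared genes and samples. Values may be
#' negative; no clipping happens here (the shift to non-negativity is part
#' of the factorization stage).
#'
#' @param bulks_scaled samples x genes matrix in `[0, 1]`, or a scaled
#'   `pseudobulk_set`.
#' @param bulk_like A [reconstruct_bulks()] result aligned with the bulks.
#' @param source_method,reference_tag Provenance strings stored on the
#'   result.
#' @return An object of class `residual_matrix` with fields `values`,
#'   `source_method`, `reference_tag`, `gene_names` and `sample_ids`.
#' @export
compute_residual <- function(bulks_scaled, bulk_like,
                             source_method = attr(bulk_like, "method") %||% "unknown",
                             reference_tag = "reference") {
  if (inherits(bulks_scaled, "pseudobulk_set")) {
    bulks_scaled <- bulks_scaled$expression
  }
  stopifnot(is.matrix(bulks_scaled), is.matrix(bulk_like))
  genes <- intersect(colnames(bulks_scaled), colnames(bulk_like))
  if (length(genes) == 0) stop("no shared genes between bulks and bulk-like")
  if (nrow(bulks_scaled) != nrow(bulk_like)) stop("sample count mismatch")
  values <- bulks_scaled[, genes, drop = FALSE] -
    bulk_like[, genes, drop = FALSE]
  structure(
    list(values = values,
         source_method = source_method,
         reference_tag = reference_tag,
         gene_names = genes,
         sample_ids = rownames(values)),
    class = "residual_matrix"
  )
}

#' Compare per-gene mean residuals between two references
#'
#' For each gene in each named gene set, computes the mean residual across
#' samples under both references. Genes above the 1:1 diagonal in
#' (`mean_a`, `mean_b`) space carry more unexplained expression under
#' reference B — the signature of a cell type missing from B.
#'
#' @param residual_a,residual_b `residual_matrix` objects over the same
#'   cohort.
#' @param gene_sets Named list of character vectors (e.g. marker lists for
#'   the suspected missing types).
#' @return Data frame with columns `gene`, `set`, `mean_a`, `mean_b`.
#' @export
compare_marker_residuals <- function(residual_a, residual_b, gene_sets) {
  stopifnot(inherits(residual_a, "residual_matrix"),
            inherits(residual_b, "residual_matrix"),
            is.list(gene_sets), length(names(gene_sets)) == length(gene_sets))
  shared <- intersect(residual_a$gene_names, residual_b$gene_names)
  out <- list()
  for (set in names(gene_sets)) {
    genes <- intersect(gene_sets[[set]], shared)
    dropped <- setdiff(gene_sets[[set]], genes)
    if (length(dropped) > 0) {
      warning(length(dropped), " gene(s) of set '", set,
              "' absent from the residuals; excluded")
    }
    if (length(genes) == 0) {
      warning("gene set '", set, "' has no genes in the residuals; skipped")
      next
    }
    out[[set]] <- data.frame(
      gene = genes,
      set = set,
      mean_a = colMeans(residual_a$values[, genes, drop = FALSE]),
      mean_b = colMeans(residual_b$values[, genes, drop = FALSE]),
      row.names = NULL
    )
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), set = character(0),
                      mean_a = numeric(0), mean_b = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
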