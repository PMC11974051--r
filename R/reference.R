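#' Build a per-cell-type signature matrix
#'
#' For each declared cell type, samples `cells_per_type` cells with
#' replacement and sums their counts per gene, giving one aggregate
#' expression row per type. The uniform cell budget standardises the
#' signature against unequal type abundances.
#'
#' @param dataset A [cell_dataset()]; every declared type needs >= 1 cell.
#' @param cells_per_type Cells sampled per type (default 10000).
#' @param seed Integer seed.
#' @return An object of class `signature_matrix` with fields `values`
#'   (types x genes), `type_names`, `gene_names`, `scaled`,
#'   `cells_per_type_used` and `removed_types`.
#' @export
build_signature <- function(dataset, cells_per_type = 10000L, seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"), cells_per_type >= 1)
  types <- dataset$type_names
  empty <- setdiff(types, unique(dataset$cell_labels))
  if (length(empty) > 0) {
    stop("no cells for type(s): ", paste(empty, collapse = ", "))
  }
  set.seed(seed)
  values <- t(vapply(types, function(t) {
    idx <- sample(which(dataset$cell_labels == t), cells_per_type,
                  replace = TRUE)
    rowSums(dataset$counts[, idx, drop = FALSE])
  }, numeric(nrow(dataset$counts))))
  dimnames(values) <- list(types, dataset$gene_names)
  structure(
    list(values = values,
         type_names = types,
         gene_names = dataset$gene_names,
         scaled = FALSE,
         cells_per_type_used = as.integer(cells_per_type),
         removed_types = character(0)),
    class = "signature_matrix"
  )
}

#' Remove cell types from a signature (incomplete-reference experiments)
#'
#' Removes named or randomly chosen types from the signature, recording the
#' cumulative removal order. At least 2 types must remain.
#'
#' @param signature A [build_signature()] result.
#' @param types_to_remove Character vector of types to drop; mutually
#'   exclusive with `n_random`.
#' @param n_random Number of types to drop uniformly at random.
#' @param seed Integer seed (used only for random removal).
#' @return A `signature_matrix` without the removed rows; `removed_types`
#'   accumulates across successive calls.
#' @export
remove_cell_types <- function(signature, types_to_remove = NULL,
                              n_random = NULL, seed = 1L) {
  stopifnot(inherits(signature, "signature_matrix"))
  if (is.null(types_to_remove) == is.null(n_random)) {
    stop("give exactly one of types_to_remove or n_random")
  }
  if (!is.null(n_random)) {
    stopifnot(n_random >= 1)
    set.seed(seed)
    types_to_remove <- sample(signature$type_names, n_random)
  }
  unknown <- setdiff(types_to_remove, signature$type_names)
  if (length(unknown) > 0) {
    stop("types not in signature: ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(signature$type_names, types_to_remove)
  if (length(keep) < 2) {
    stop("removal would leave fewer than 2 cell types in the reference")
  }
  signature$values <- signature$values[keep, , drop = FALSE]
  signature$type_names <- keep
  signature$removed_types <- c(signature$removed_types, types_to_remove)
  signature
}

#' Select cell-type marker genes by specificity
#'
#' For every gene, the specificity for a type is its signature expression
#' divided by the gene's total expression across types (plus a small
#' epsilon). Each type contributes its `n_per_type` most specific genes,
#' ties broken by higher absolute expression and then by gene order. This is
#' a transparent stand-in for externally computed barcode/marker gene lists;
#' use [marker_gene_set()] to supply such a list instead.
#'
#' @param signature An unscaled [build_signature()] result.
#' @param n_per_type Markers per type (default 150).
#' @return An object of class `marker_gene_set` with `per_type` lists and
#'   their `union`.
#' @export
select_marker_genes <- function(signature, n_per_type = 150L) {
  stopifnot(inherits(signature, "signature_matrix"), n_per_type >= 1)
  if (signature$scaled) {
    stop("marker selection needs the unscaled signature")
  }
  v <- signature$values
  totals <- colSums(v)
  specificity <- sweep(v, 2, totals + 1e-12, "/")
  n_genes <- ncol(v)
  if (n_per_type > n_genes) {
    warning("requested ", n_per_type, " markers per type but only ",
            n_genes, " genes available; returning all")
    n_per_type <- n_genes
  }
  per_type <- lapply(signature$type_names, function(t) {
    ord <- order(-specificity[t, ], -v[t, ])  # stable: gene order breaks ties
    signature$gene_names[ord[seq_len(n_per_type)]]
  })
  names(per_type) <- signature$type_names
  marker_gene_set(per_type)
}

#' Construct a marker gene set from explicit gene lists
#'
#' @param per_type Named list of character vectors (one per cell type), or a
#'   single character vector used as an unstructured union.
#' @return An object of class `marker_gene_set`.
#' @export
marker_gene_set <- function(per_type) {
  if (is.character(per_type)) per_type <- list(all = per_type)
  stopifnot(is.list(per_type), all(vapply(per_type, length, 1L) > 0))
  structure(
    list(per_type = per_type,
         union = unique(unlist(per_type, use.names = FALSE))),
    class = "marker_gene_set"
  )
}

#' Clip extreme values and MinMax-scale a matrix to `[0, 1]`
#'
#' Values above the matrix-wide `clip_percentile`-th percentile (linear
#' interpolation) are winsorised to that percentile, so a handful of very
#' high-expressed entries cannot dominate the scale. The whole matrix is
#' then rescaled by one global `(x - min) / (max - min)`. A constant matrix
#' maps to all zeros. Scaling is matrix-global rather than per-gene so the
#' linear mixture relation between bulks and the signature is preserved.
#'
#' @param x Numeric matrix (>= 0), `signature_matrix` or `pseudobulk_set`.
#' @param clip_percentile Percentile above which values are clipped
#'   (default 95).
#' @return Same class as the input, with values in `[0, 1]` (signatures get
#'   `scaled = TRUE`).
#' @export
clip_and_minmax <- function(x, clip_percentile = 95) {
  UseMethod("clip_and_minmax")
}

#' @export
clip_and_minmax.matrix <- function(x, clip_percentile = 95) {
  if (length(x) == 0) stop("empty matrix")
  if (any(x < 0)) stop("clip_and_minmax expects non-negative input")
  stopifnot(clip_percentile > 0, clip_percentile <= 100)
  th <- quantile(x, clip_percentile / 100, names = FALSE)  # type 7: linear
  x[x > th] <- th
  rng <- range(x)
  if (rng[2] == rng[1]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
clip_and_minmax.signature_matrix <- function(x, clip_percentile = 95) {
  x$values <- clip_and_minmax(x$values, clip_percentile)
  x$scaled <- TRUE
  x
}

#' @export
clip_and_minmax.pseudobulk_set <- function(x, clip_percentile = 95) {
  x$expression <- clip_and_minmax(x$expression, clip_percentile)
  x
}
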