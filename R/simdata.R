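#' Similarity specification for synthetic cell-type profiles
#'
#' Bundles the knobs that control how distinguishable the synthetic cell
#' types are. Each type receives a disjoint block of marker genes elevated
#' above a heavy-tailed per-type baseline; the per-type profiles are then
#' blended convexly towards their common mean profile, with the blend weight
#' solved numerically so that the realised pairwise Pearson correlation of
#' the mean profiles matches `target_correlation`. Blending both raises the
#' profile correlation and dilutes marker specificity, as in
#' transcriptionally similar cell types.
#'
#' @param target_correlation Desired off-diagonal Pearson correlation of the
#'   per-type mean expression profiles, in `[0, 1)`. `0` emulates distinct
#'   cell types, values near `0.8` emulate transcriptionally similar types.
#' @param n_marker_genes_per_type Number of genes in each type's disjoint
#'   marker block (default 200).
#' @param baseline_expression Mean of the per-gene, per-type baseline
#'   expression (expected counts per cell; default 0.5).
#' @param marker_expression Mean elevation of marker genes above baseline
#'   (expected counts per cell; default 2).
#' @param baseline_sdlog Log-scale standard deviation of the lognormal
#'   baseline, controlling how heavy-tailed the expression distribution is
#'   (default 1).
#' @return An object of class `similarity_spec`.
#' @export
similarity_spec <- function(target_correlation = 0,
                            n_marker_genes_per_type = 200,
                            baseline_expression = 0.5,
                            marker_expression = 2,
                            baseline_sdlog = 1) {
  stopifnot(length(target_correlation) == 1, is.numeric(target_correlation))
  if (target_correlation < 0 || target_correlation >= 1) {
    stop("target_correlation must lie in [0, 1): a correlation of 1 would ",
         "make cell types indistinguishable")
  }
  stopifnot(n_marker_genes_per_type >= 1,
            baseline_expression >= 0,
            marker_expression >= 0,
            baseline_sdlog >= 0)
  structure(
    list(target_correlation = target_correlation,
         n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
         baseline_expression = baseline_expression,
         marker_expression = marker_expression,
         baseline_sdlog = baseline_sdlog),
    class = "similarity_spec"
  )
}

# lognormal draws with a given arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  if (mean <= 0) return(rep(0, n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

mean_offdiag_cor <- function(m) {
  cc <- suppressWarnings(cor(t(m)))
  mean(cc[upper.tri(cc)], na.rm = TRUE)
}

#' Generate synthetic cell-type mean expression profiles
#'
#' Builds `n_types` mean expression profiles over `n_genes` genes. Each type
#' has: (i) an independent heavy-tailed lognormal baseline per gene, and
#' (ii) a disjoint block of elevated marker genes. The per-type profiles are
#' then blended convexly towards their common mean profile; the blend weight
#' is solved numerically ([stats::uniroot()]) so the realised mean
#' off-diagonal Pearson correlation of the profiles equals the target.
#'
#' @param n_types Number of cell types (at least 2).
#' @param n_genes Number of genes; must be at least
#'   `n_types * n_marker_genes_per_type`.
#' @param similarity A [similarity_spec()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param type_names Optional character vector of type labels.
#' @return An object of class `cell_profiles` with fields `type_names`,
#'   `mean_profiles` (types x genes), `gene_names`, `marker_genes` (named
#'   list of designed marker genes per type) and `blend_weight`.
#' @export
generate_cell_profiles <- function(n_types, n_genes,
                                   similarity = similarity_spec(),
                                   seed = 1L,
                                   type_names = NULL) {
  stopifnot(inherits(similarity, "similarity_spec"))
  n_types <- as.integer(n_types)
  n_genes <- as.integer(n_genes)
  if (n_types < 2) stop("n_types must be >= 2")
  nm <- similarity$n_marker_genes_per_type
  if (n_genes < n_types * nm) {
    stop("n_genes must be >= n_types * n_marker_genes_per_type (",
         n_types * nm, ")")
  }
  if (is.null(type_names)) type_names <- paste0("type", seq_len(n_types))
  stopifnot(length(type_names) == n_types, !anyDuplicated(type_names))
  gene_names <- sprintf("gene%05d", seq_len(n_genes))

  set.seed(seed)
  baseline <- matrix(
    rlnorm_mean(n_types * n_genes, similarity$baseline_expression,
                similarity$baseline_sdlog),
    nrow = n_types, ncol = n_genes
  )
  marker <- matrix(0, n_types, n_genes)
  blocks <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    idx <- ((t - 1L) * nm + 1L):(t * nm)
    blocks[[t]] <- gene_names[idx]
    # mean-1 lognormal jitter keeps expected elevation = marker_expression
    marker[t, idx] <- similarity$marker_expression * rlnorm_mean(nm, 1, 0.5)
  }
  names(blocks) <- type_names
  base <- baseline + marker
  common <- colMeans(base)

  profiles_at <- function(w) {
    (1 - w) * base + w * matrix(common, n_types, n_genes, byrow = TRUE)
  }
  target <- similarity$target_correlation
  f <- function(w) mean_offdiag_cor(profiles_at(w)) - target
  if (f(0) >= 0) {
    w <- 0
  } else {
    upper <- 1 - 1e-6
    if (f(upper) < 0) stop("could not reach target correlation ", target)
    w <- uniroot(f, c(0, upper), tol = 1e-8)$root
  }

  profiles <- profiles_at(w)
  dimnames(profiles) <- list(type_names, gene_names)
  structure(
    list(type_names = type_names,
         mean_profiles = profiles,
         gene_names = gene_names,
         marker_genes = blocks,
         blend_weight = w,
         similarity = similarity),
    class = "cell_profiles"
  )
}

#' Construct a single-cell count dataset
#'
#' Lightweight validated container for a genes x cells integer count matrix
#' with one cell-type label per cell.
#'
#' @param counts genes x cells matrix of non-negative integers with gene
#'   rownames and cell colnames.
#' @param cell_labels Character vector of cell-type labels, one per column.
#' @param type_names Declared cell-type universe; defaults to the labels'
#'   unique values in order of first appearance.
#' @param provenance Free-text tag, e.g. `"sc"` or `"sn"`.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(counts, cell_labels, type_names = NULL,
                         provenance = "sn") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(cell_labels) != ncol(counts)) {
    stop("need one cell label per column of counts")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene names: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
  }
  cell_labels <- as.character(cell_labels)
  if (is.null(type_names)) type_names <- unique(cell_labels)
  if (!all(cell_labels %in% type_names)) {
    stop("cell labels outside the declared type set: ",
         paste(setdiff(cell_labels, type_names), collapse = ", "))
  }
  structure(
    list(counts = counts,
         cell_labels = cell_labels,
         gene_names = rownames(counts),
         type_names = type_names,
         provenance = provenance),
    class = "cell_dataset"
  )
}

#' Sample overdispersed single-cell counts from mean profiles
#'
#' Draws per-cell counts from a negative-binomial law with each type's mean
#' profile and a shared dispersion, the standard overdispersed count model
#' for scRNA-seq (variance = mu + dispersion * mu^2).
#'
#' @param profiles A [generate_cell_profiles()] result.
#' @param n_cells_per_type Integer, or named integer vector per type.
#' @param dispersion Negative-binomial dispersion (> 0; default 0.3).
#' @param seed Integer seed.
#' @param provenance Tag stored on the dataset.
#' @return A [cell_dataset()] with cells in type-contiguous blocks.
#' @export
sample_cells <- function(profiles, n_cells_per_type, dispersion = 0.3,
                         seed = 1L, provenance = "sn") {
  stopifnot(inherits(profiles, "cell_profiles"), dispersion > 0)
  k <- length(profiles$type_names)
  if (length(n_cells_per_type) == 1) {
    n_cells_per_type <- rep(as.integer(n_cells_per_type), k)
  }
  stopifnot(length(n_cells_per_type) == k, all(n_cells_per_type >= 1))
  n_genes <- length(profiles$gene_names)
  set.seed(seed)
  mats <- vector("list", k)
  for (t in seq_len(k)) {
    n <- n_cells_per_type[t]
    mu <- profiles$mean_profiles[t, ]
    m <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                nrow = n_genes, ncol = n)
    mats[[t]] <- m
  }
  counts <- do.call(cbind, mats)
  rownames(counts) <- profiles$gene_names
  colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
  labels <- rep(profiles$type_names, times = n_cells_per_type)
  cell_dataset(counts, labels, type_names = profiles$type_names,
               provenance = provenance)
}

#' Pair a complete single-nucleus dataset with a depleted single-cell one
#'
#' Emulates the loss of dissociation-sensitive cell types (e.g. adipocytes)
#' in single-cell protocols relative to single-nucleus protocols: the `sn`
#' arm is the input unchanged; in the `sc` arm each cell of a depleted type
#' is independently dropped with probability `depletion_rate`.
#'
#' @param dataset A [cell_dataset()].
#' @param depleted_types Character vector of types to deplete.
#' @param depletion_rate Per-cell drop probability in `[0, 1]`; `1` removes
#'   the types entirely.
#' @param seed Integer seed.
#' @return A list with elements `sc` and `sn`, both [cell_dataset()]s.
#' @export
make_paired_sc_sn <- function(dataset, depleted_types, depletion_rate,
                              seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"),
            depletion_rate >= 0, depletion_rate <= 1)
  if (!all(depleted_types %in% dataset$type_names)) {
    stop("unknown depleted types: ",
         paste(setdiff(depleted_types, dataset$type_names), collapse = ", "))
  }
  set.seed(seed)
  drop <- dataset$cell_labels %in% depleted_types &
    runif(length(dataset$cell_labels)) < depletion_rate
  if (all(drop)) stop("depletion would leave an empty single-cell dataset")
  keep <- !drop
  sc <- cell_dataset(dataset$counts[, keep, drop = FALSE],
                     dataset$cell_labels[keep],
                     type_names = dataset$type_names,
                     provenance = "sc")
  sn <- dataset
  sn$provenance <- "sn"
  list(sc = sc, sn = sn)
}

#' Pairwise Pearson correlation of per-type expression profiles
#'
#' For a `cell_profiles` object the correlation is computed on the mean
#' profiles; for a `cell_dataset` on the per-type mean of the observed
#' counts. A type with a zero-variance profile yields `NA` against every
#' other type.
#'
#' @param x A `cell_profiles` or `cell_dataset`.
#' @return A symmetric types x types correlation matrix with unit diagonal
#'   (where defined).
#' @export
profile_similarity <- function(x) {
  if (inherits(x, "cell_profiles")) {
    m <- x$mean_profiles
  } else if (inherits(x, "cell_dataset")) {
    types <- x$type_names
    if (length(types) < 2) stop("need at least 2 cell types")
    m <- t(vapply(types, function(t) {
      rowMeans(x$counts[, x$cell_labels == t, drop = FALSE])
    }, numeric(nrow(x$counts))))
    rownames(m) <- types
  } else {
    stop("x must be a cell_profiles or cell_dataset")
  }
  if (nrow(m) < 2) stop("need at least 2 cell types")
  cc <- suppressWarnings(cor(t(m)))
  # zero-variance rows produce NA off-diagonal; keep a defined diagonal
  diag(cc)[apply(m, 1, function(r) var(r) > 0)] <- 1
  cc
}
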