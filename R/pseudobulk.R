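#' Noise specification for pseudobulk construction
#'
#' @param libsize_sd Standard deviation of the per-sample multiplicative
#'   library-size scale, centred at 1 (default 0.1).
#' @param gene_sd_frac Per-entry additive Gaussian standard deviation,
#'   expressed as a fraction of the entry's value (default 0.05).
#' @param proportion_sd Per-type Gaussian standard deviation used when
#'   drawing realistic proportions around a base composition (default 0.05).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(libsize_sd = 0.1, gene_sd_frac = 0.05,
                       proportion_sd = 0.05) {
  stopifnot(libsize_sd >= 0, gene_sd_frac >= 0, proportion_sd >= 0)
  structure(list(libsize_sd = libsize_sd,
                 gene_sd_frac = gene_sd_frac,
                 proportion_sd = proportion_sd),
            class = "noise_spec")
}

validate_proportions <- function(p, tol = 1e-9) {
  stopifnot(is.matrix(p))
  if (any(p < 0)) stop("proportions must be non-negative")
  if (any(abs(rowSums(p) - 1) > tol)) {
    stop("proportion rows must sum to 1 (tolerance ", tol, ")")
  }
  invisible(p)
}

#' Draw random cell-type proportions on the simplex
#'
#' Each row is an independent vector of uniform(0,1) draws divided by its
#' sum, so proportions span nearly the whole 0-1 range across samples.
#'
#' @param n_samples,n_types Dimensions of the proportion matrix.
#' @param seed Integer seed.
#' @param type_names,sample_ids Optional dimension names.
#' @return A samples x types matrix with non-negative rows summing to 1.
#' @export
draw_random_proportions <- function(n_samples, n_types, seed = 1L,
                                    type_names = NULL, sample_ids = NULL) {
  stopifnot(n_samples >= 1, n_types >= 1)
  set.seed(seed)
  p <- matrix(runif(n_samples * n_types), nrow = n_samples)
  p <- p / rowSums(p)
  rownames(p) <- sample_ids %||% sprintf("bulk%04d", seq_len(n_samples))
  colnames(p) <- type_names %||% paste0("type", seq_len(n_types))
  validate_proportions(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw realistic cell-type proportions around a base composition
#'
#' Per sample and type, adds Gaussian noise to the base proportion, clips
#' negatives to zero and renormalises the row to sum to 1. Rows that clip
#' to all-zero are redrawn (bounded retries).
#'
#' @param base_proportions Named non-negative vector summing to 1.
#' @param n_samples Number of samples.
#' @param noise A [noise_spec()]; only `proportion_sd` is used.
#' @param seed Integer seed.
#' @param max_retries Redraw budget for degenerate all-zero rows.
#' @return A samples x types proportion matrix.
#' @export
draw_realistic_proportions <- function(base_proportions, n_samples,
                                       noise = noise_spec(), seed = 1L,
                                       max_retries = 100L) {
  stopifnot(inherits(noise, "noise_spec"), n_samples >= 1)
  if (abs(sum(base_proportions) - 1) > 1e-9 || any(base_proportions < 0)) {
    stop("base_proportions must be non-negative and sum to 1")
  }
  k <- length(base_proportions)
  sd <- noise$proportion_sd
  set.seed(seed)
  p <- matrix(NA_real_, n_samples, k)
  for (i in seq_len(n_samples)) {
    for (try in seq_len(max_retries)) {
      row <- pmax(base_proportions + rnorm(k, 0, sd), 0)
      if (sum(row) > 0) break
      row <- NULL
    }
    if (is.null(row)) stop("could not draw a non-degenerate proportion row")
    p[i, ] <- row / sum(row)
  }
  rownames(p) <- sprintf("bulk%04d", seq_len(n_samples))
  colnames(p) <- names(base_proportions) %||% paste0("type", seq_len(k))
  validate_proportions(p)
  p
}

#' Convert a proportion row to integer cell counts
#'
#' Largest-remainder rounding of `row * total_cells`: floors are taken
#' first and the leftover cells go to the types with the largest fractional
#' parts (ties broken by type order), so the counts always sum exactly to
#' `total_cells`.
#'
#' @param row Proportion vector summing to 1.
#' @param total_cells Total cell budget per pseudobulk (default 5000).
#' @return Integer vector summing exactly to `total_cells`.
#' @export
proportions_to_counts <- function(row, total_cells = 5000L) {
  stopifnot(total_cells >= 1, all(row >= 0))
  if (abs(sum(row) - 1) > 1e-9) stop("row must sum to 1")
  raw <- row * total_cells
  counts <- floor(raw)
  remainder <- as.integer(round(total_cells - sum(counts)))
  if (remainder > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(remainder)]
    counts[top] <- counts[top] + 1
  }
  storage.mode(counts) <- "integer"
  names(counts) <- names(row)
  counts
}

#' Build pseudobulks with known ground-truth proportions
#'
#' For each sample, the proportion row is converted to per-type cell counts
#' with a fixed total budget, that many cells are sampled with replacement
#' from the dataset within each type, and their counts are summed per gene.
#'
#' @param dataset A [cell_dataset()] containing every type in `truth`.
#' @param truth samples x types proportion matrix (rows sum to 1).
#' @param total_cells Cells per pseudobulk (default 5000).
#' @param seed Integer seed.
#' @return An object of class `pseudobulk_set` with fields `expression`
#'   (samples x genes), `truth`, `total_cells_per_sample`, `noise_applied`
#'   and `gene_names`.
#' @export
build_pseudobulks <- function(dataset, truth, total_cells = 5000L,
                              seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  validate_proportions(truth)
  types <- colnames(truth)
  missing <- setdiff(types, unique(dataset$cell_labels))
  if (length(missing) > 0) {
    stop("cell types absent from the dataset: ",
         paste(missing, collapse = ", "))
  }
  type_cells <- lapply(types, function(t) which(dataset$cell_labels == t))
  names(type_cells) <- types
  set.seed(seed)
  n_samples <- nrow(truth)
  expr <- matrix(0, n_samples, nrow(dataset$counts),
                 dimnames = list(rownames(truth), dataset$gene_names))
  for (i in seq_len(n_samples)) {
    alloc <- proportions_to_counts(truth[i, ], total_cells)
    names(alloc) <- types
    idx <- unlist(lapply(types, function(t) {
      if (alloc[[t]] == 0) return(integer(0))
      sample(type_cells[[t]], alloc[[t]], replace = TRUE)
    }), use.names = FALSE)
    expr[i, ] <- rowSums(dataset$counts[, idx, drop = FALSE])
  }
  structure(
    list(expression = expr,
         truth = truth,
         total_cells_per_sample = as.integer(total_cells),
         noise_applied = FALSE,
         gene_names = dataset$gene_names),
    class = "pseudobulk_set"
  )
}

#' Add library-size and per-gene Gaussian noise to pseudobulks
#'
#' Each sample is multiplied by an independent Gaussian(1, `libsize_sd`)
#' scale, then each entry is perturbed by Gaussian noise with standard
#' deviation `gene_sd_frac` times the entry's value. Negative results are
#' clipped to zero.
#'
#' @param bulks A [build_pseudobulks()] result.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A `pseudobulk_set` with `noise_applied = TRUE`.
#' @export
add_bulk_noise <- function(bulks, noise = noise_spec(), seed = 1L) {
  stopifnot(inherits(bulks, "pseudobulk_set"), inherits(noise, "noise_spec"))
  set.seed(seed)
  expr <- bulks$expression
  scales <- rnorm(nrow(expr), mean = 1, sd = noise$libsize_sd)
  expr <- expr * scales
  if (noise$gene_sd_frac > 0) {
    expr <- expr + rnorm(length(expr), 0, noise$gene_sd_frac * abs(expr))
  }
  expr[expr < 0] <- 0
  bulks$expression <- expr
  bulks$noise_applied <- TRUE
  bulks
}
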