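# Cohort-level residual comparisons: per-factor group tests, distribution
# tests on gene-set residuals, and PCA of residuals with loading-ranked
# gene lists.

check_groups <- function(group_labels, n_samples) {
  group_labels <- as.character(group_labels)
  if (length(group_labels) != n_samples) {
    stop("need one group label per sample")
  }
  levels <- unique(group_labels)
  if (length(levels) != 2) stop("exactly two groups are required")
  sizes <- table(group_labels)
  if (any(sizes < 2)) stop("each group needs at least 2 samples")
  group_labels
}

bonferroni_report <- function(component, raw_p, alpha) {
  k <- length(raw_p)
  adj <- pmin(1, raw_p * k)
  data.frame(component = component,
             p_raw = raw_p,
             p_bonferroni = adj,
             significant = adj < alpha,
             row.names = NULL)
}

#' Test NMF factor weights for differences between two sample groups
#'
#' Welch two-sample t-test on each factor's sample weights between the two
#' groups, Bonferroni-corrected across the k factors. A factor that is
#' significant only when the reference lacks a cell type carries that
#' missing type's signal.
#'
#' @param factorization A [factorize_residual()] result computed on the
#'   combined cohort residual.
#' @param group_labels One of two labels per sample, in the residual's
#'   sample order.
#' @param alpha Significance level after correction (default 0.05).
#' @return An object of class `component_test_report`: data frame with
#'   columns `component`, `p_raw`, `p_bonferroni`, `significant`, plus the
#'   per-sample scores in `attr(, "scores")`.
#' @export
compare_factor_weights <- function(factorization, group_labels,
                                   alpha = 0.05) {
  stopifnot(inherits(factorization, "factorization_result"))
  w <- factorization$sample_weights
  group_labels <- check_groups(group_labels, nrow(w))
  levels <- unique(group_labels)
  raw_p <- apply(w, 2, function(x) {
    a <- x[group_labels == levels[1]]
    b <- x[group_labels == levels[2]]
    if (var(a) == 0 && var(b) == 0) return(1)  # identical weights: no signal
    t.test(a, b)$p.value
  })
  rep <- bonferroni_report(colnames(w), unname(raw_p), alpha)
  attr(rep, "scores") <- w
  attr(rep, "alpha") <- alpha
  class(rep) <- c("component_test_report", class(rep))
  rep
}

#' Compare residual distributions over a gene set between two residuals
#'
#' Pools the residual values of the gene set's genes in each residual and
#' compares the two collections with a rank-based two-sample test
#' (Wilcoxon rank-sum by default; `paired = TRUE` gives the signed-rank
#' test for matched cohorts).
#'
#' @param residual_a,residual_b `residual_matrix` objects.
#' @param gene_set Character vector of genes.
#' @param paired Use the paired signed-rank test (default FALSE).
#' @return List with `statistic`, `p_value`, `n_genes` and `method`.
#' @export
compare_residual_distributions <- function(residual_a, residual_b, gene_set,
                                           paired = FALSE) {
  stopifnot(inherits(residual_a, "residual_matrix"),
            inherits(residual_b, "residual_matrix"))
  genes <- Reduce(intersect, list(gene_set, residual_a$gene_names,
                                  residual_b$gene_names))
  if (length(genes) == 0) stop("gene_set shares no genes with the residuals")
  a <- as.vector(residual_a$values[, genes, drop = FALSE])
  b <- as.vector(residual_b$values[, genes, drop = FALSE])
  ht <- wilcox.test(a, b, paired = paired, exact = FALSE)
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n_genes = length(genes),
       method = ht$method)
}

#' PCA of a cohort residual with group tests and gene loadings
#'
#' Mean-centred PCA of the residual (samples x genes). Loadings per
#' component are the component vector times the square root of that
#' component's explained variance, so high-loading genes are those driving
#' the most residual variation. Signs are fixed so each component's
#' largest-magnitude loading is positive. If group labels are given, each
#' component's scores are compared between groups with a Welch t-test and
#' Bonferroni correction.
#'
#' @param residual A `residual_matrix` (or samples x genes matrix).
#' @param group_labels Optional two-level labels per sample.
#' @param n_components Number of components (default 8).
#' @param alpha Significance level (default 0.05).
#' @return List with `scores` (samples x k), `loadings` (genes x k),
#'   `explained_variance` (length-k eigenvalues) and `tests`
#'   (a `component_test_report`, or `NULL` without groups).
#' @export
pca_residuals <- function(residual, group_labels = NULL, n_components = 8L,
                          alpha = 0.05) {
  values <- if (inherits(residual, "residual_matrix")) residual$values
            else residual
  stopifnot(is.matrix(values))
  k_max <- min(nrow(values) - 1L, ncol(values))
  if (n_components > k_max) {
    stop("n_components must be <= min(samples - 1, genes) = ", k_max)
  }
  pc <- prcomp(values, center = TRUE, scale. = FALSE)
  k <- as.integer(n_components)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev[seq_len(k)]^2
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, sqrt(ev), "*")
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  tests <- NULL
  if (!is.null(group_labels)) {
    group_labels <- check_groups(group_labels, nrow(values))
    levels <- unique(group_labels)
    raw_p <- apply(scores, 2, function(x) {
      a <- x[group_labels == levels[1]]
      b <- x[group_labels == levels[2]]
      if (var(a) == 0 && var(b) == 0) return(1)
      t.test(a, b)$p.value
    })
    tests <- bonferroni_report(colnames(scores), unname(raw_p), alpha)
    attr(tests, "scores") <- scores
    attr(tests, "alpha") <- alpha
    class(tests) <- c("component_test_report", class(tests))
  }
  list(scores = scores,
       loadings = loadings,
       explained_variance = ev,
       tests = tests)
}

#' Rank genes by their loading on one component
#'
#' Sorts genes by descending loading value (ties broken by gene order), the
#' format expected by ranked-list gene ontology tools.
#'
#' @param loadings genes x components matrix (from [pca_residuals()], or any
#'   loading matrix with gene rownames).
#' @param component Component index or name.
#' @return Character vector of gene names, most-contributing first.
#' @export
rank_genes_by_loading <- function(loadings, component) {
  stopifnot(is.matrix(loadings))
  l <- loadings[, component]
  rownames(loadings)[order(-l)]  # order() is stable: gene order breaks ties
}

#' Write a ranked gene list to disk
#'
#' One gene per line, in the given order.
#'
#' @param genes Character vector (e.g. from [rank_genes_by_loading()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
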