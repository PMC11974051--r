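make_residual <- function(values, tag = "x") {
  structure(list(values = values, source_method = "nnls",
                 reference_tag = tag, gene_names = colnames(values),
                 sample_ids = rownames(values)),
            class = "residual_matrix")
}

test_that("factor-weight group tests apply exact Bonferroni correction", {
  set.seed(12)
  w <- matrix(rexp(20 * 4), 20, 4,
              dimnames = list(paste0("s", 1:20), paste0("factor", 1:4)))
  w[1:10, 2] <- w[1:10, 2] + 50  # one factor strongly separates the groups
  fz <- structure(list(sample_weights = w, k = 4L),
                  class = "factorization_result")
  groups <- rep(c("dissociated", "classic"), each = 10)
  rep_ <- compare_factor_weights(fz, groups, alpha = 0.05)
  expect_equal(rep_$p_bonferroni, pmin(1, rep_$p_raw * 4))
  expect_identical(rep_$significant, rep_$p_bonferroni < 0.05)
  expect_true(rep_$significant[2])

  # identical weights in both groups: no signal, not significant
  w2 <- w
  w2[, 1] <- rep(c(1, 2), 10)
  fz2 <- structure(list(sample_weights = w2, k = 4L),
                   class = "factorization_result")
  rep2 <- compare_factor_weights(fz2, rep(c("a", "b"), 10))
  expect_false(rep2$significant[1])

  expect_error(compare_factor_weights(fz, rep("a", 20)), "two groups")
  expect_error(compare_factor_weights(fz, c("a", rep("b", 19))),
               "at least 2")
})

test_that("gene-set residual distributions are compared by rank tests", {
  set.seed(13)
  v <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:30)))
  ra <- make_residual(v)
  rb <- make_residual(v)
  same <- compare_residual_distributions(ra, rb, paste0("g", 1:10))
  expect_gt(same$p_value, 0.9)
  expect_equal(same$n_genes, 10)

  shifted <- make_residual(v + 5)
  diff <- compare_residual_distributions(ra, shifted, paste0("g", 1:10))
  expect_lt(diff$p_value, 0.05)

  expect_error(compare_residual_distributions(ra, rb, c("nope")), "no genes")

  paired <- compare_residual_distributions(ra, shifted, paste0("g", 1:10),
                                           paired = TRUE)
  expect_match(paired$method, "signed rank")
})

test_that("residual PCA yields sqrt-eigenvalue loadings and exact reconstruction", {
  # 5 x 6 toy checked against a covariance eigendecomposition oracle
  set.seed(14)
  x <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:6)))
  out <- pca_residuals(make_residual(x), n_components = 4)
  eig <- eigen(cov(x))
  expect_equal(out$explained_variance, eig$values[1:4], tolerance = 1e-8)
  # loading column norms equal sqrt(eigenvalue) since components are unit
  expect_equal(unname(sqrt(colSums(out$loadings^2))),
               sqrt(eig$values[1:4]), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each component is +
  for (j in 1:4) {
    expect_gt(out$loadings[which.max(abs(out$loadings[, j])), j], 0)
  }
  # full-rank reconstruction reproduces the centred matrix
  centred <- scale(x, center = TRUE, scale = FALSE)
  full <- pca_residuals(make_residual(x), n_components = 4)
  recon <- full$scores %*% t(sweep(full$loadings, 2,
                                   sqrt(full$explained_variance), "/"))
  expect_lt(max(abs(recon - centred)), 1e-8)

  # exact rank-2 data: trailing explained variance vanishes
  r2 <- tcrossprod(matrix(rnorm(10), 5, 2), matrix(rnorm(12), 6, 2))
  dimnames(r2) <- dimnames(x)
  out2 <- pca_residuals(make_residual(r2), n_components = 4)
  expect_lt(max(out2$explained_variance[3:4]), 1e-10)

  # duplicated cohort: identical groups show no significant components
  dup <- rbind(x, x)
  rownames(dup) <- paste0("s", 1:10)
  out3 <- pca_residuals(make_residual(dup),
                        group_labels = rep(c("a", "b"), each = 5),
                        n_components = 3)
  expect_false(any(out3$tests$significant))

  expect_error(pca_residuals(make_residual(x), n_components = 10),
               "n_components")
})

test_that("gene ranking by loading is a deterministic permutation", {
  l <- matrix(c(0.1, 5, -0.2, 0.3,
                1, 1, 1, 2), 4, 2,
              dimnames = list(paste0("g", 1:4), c("PC1", "PC2")))
  ranked <- rank_genes_by_loading(l, "PC1")
  expect_equal(ranked[1], "g2")
  expect_setequal(ranked, rownames(l))
  # ties broken by gene order
  expect_equal(rank_genes_by_loading(l, "PC2"), c("g4", "g1", "g2", "g3"))

  f <- tempfile(fileext = ".txt")
  write_gene_list(ranked, f)
  expect_identical(readLines(f), ranked)
})
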