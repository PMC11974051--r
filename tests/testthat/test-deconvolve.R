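make_sig <- function(values) {
  structure(list(values = values, type_names = rownames(values),
                 gene_names = colnames(values), scaled = TRUE,
                 cells_per_type_used = NA_integer_,
                 removed_types = character(0)),
            class = "signature_matrix")
}

test_that("NNLS solves exact and degenerate systems", {
  sig <- make_sig(matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("g1", "g2"))))
  bulks <- matrix(c(0.3, 0.7), 1, 2, dimnames = list("s1", c("g1", "g2")))
  dec <- nnls_deconvolve(bulks, sig)
  expect_equal(unname(dec$proportions["s1", ]), c(0.3, 0.7))
  expect_equal(unname(dec$raw_coefficients["s1", ]), c(0.3, 0.7))

  zero <- matrix(0, 1, 2, dimnames = list("z", c("g1", "g2")))
  dz <- nnls_deconvolve(zero, sig)
  expect_true(all(dz$proportions == 0))
  expect_true("z" %in% dz$zero_samples)

  # forward-constructed mixtures are recovered to 1e-6
  set.seed(3)
  s <- matrix(runif(5 * 40), 5, 40,
              dimnames = list(paste0("t", 1:5), paste0("g", 1:40)))
  s <- s / max(s)
  p <- draw_random_proportions(8, 5, seed = 4, type_names = rownames(s))
  b <- p %*% s
  rec <- nnls_deconvolve(b, make_sig(s))
  expect_lt(max(abs(rec$proportions - p)), 1e-6)

  # proportions are invariant to a global positive rescaling of the bulks
  rec_half <- nnls_deconvolve(b / 2, make_sig(s))
  expect_equal(rec_half$proportions, rec$proportions, tolerance = 1e-10)

  unscaled <- make_sig(s)
  unscaled$scaled <- FALSE
  expect_error(nnls_deconvolve(b, unscaled), "scaled")
  expect_error(nnls_deconvolve(b * 3, make_sig(s)), "\\[0, 1\\]")
})

test_that("marker filtering restricts the regression genes", {
  sc <- make_scenario(seed = 21, n_genes = 400, n_cells = 40, n_samples = 5,
                      markers_per_type = 20)
  bs <- clip_and_minmax(sc$bulks)
  ss <- clip_and_minmax(sc$signature)
  dec <- nnls_deconvolve(bs, ss, sc$markers)
  expect_setequal(dec$genes_used,
                  intersect(sc$markers$union, colnames(bs$expression)))
  expect_true(all(abs(rowSums(dec$proportions) - 1) < 1e-9))

  few <- marker_gene_set(list(all = "gene00001"))
  expect_error(nnls_deconvolve(bs, ss, few), "fewer than 2")
})

test_that("proportion evaluation matches hand-computed metrics", {
  est <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B")))
  ev <- evaluate_proportions(est, est)
  expect_equal(ev$pooled$r, 1)
  expect_equal(ev$pooled$rmse, 0)

  shifted <- est + 0.1
  ev2 <- evaluate_proportions(shifted, est)
  expect_equal(ev2$pooled$rmse, 0.1)
  expect_equal(ev2$pooled$r, 1)

  # 4-pair table, brute-force formulas
  e <- c(0.1, 0.4, 0.3, 0.2)
  t_ <- c(0.2, 0.3, 0.4, 0.1)
  em <- matrix(e, 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  tm <- matrix(t_, 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  r_manual <- sum((e - mean(e)) * (t_ - mean(t_))) /
    sqrt(sum((e - mean(e))^2) * sum((t_ - mean(t_))^2))
  rmse_manual <- sqrt(mean((e - t_)^2))
  ev3 <- evaluate_proportions(em, tm)
  expect_equal(ev3$pooled$r, r_manual, tolerance = 1e-12)
  expect_equal(ev3$pooled$rmse, rmse_manual, tolerance = 1e-12)

  # a type absent from the estimate counts as estimated zero
  ev4 <- evaluate_proportions(em[, "A", drop = FALSE], tm)
  expect_equal(ev4$pooled$rmse,
               sqrt(mean(c((e[1:2] - t_[1:2])^2, t_[3:4]^2))))

  # zero-variance estimates: r undefined, RMSE still computed
  flat <- matrix(0.5, 2, 2, dimnames = dimnames(tm))
  ev5 <- evaluate_proportions(flat, tm)
  expect_true(is.na(ev5$pooled$r))
  expect_false(is.na(ev5$pooled$rmse))
})

test_that("external proportion matrices are validated and round-trip", {
  p <- draw_random_proportions(4, 3, seed = 5)
  ext <- register_external_proportions("bayesprism", p)
  expect_equal(ext$method_name, "bayesprism")
  expect_equal(ext$proportions, p)

  slightly <- p
  slightly[1, ] <- slightly[1, ] * 1.004
  renorm <- register_external_proportions("x", slightly)
  expect_true(all(abs(rowSums(renorm$proportions) - 1) < 1e-12))

  half <- p
  half[2, ] <- half[2, ] / 2
  expect_error(register_external_proportions("x", half), "1%")
  neg <- p
  neg[1, 1] <- -0.1
  expect_error(register_external_proportions("x", neg), "non-negative")

  # CSV round trip through the adapter
  f <- tempfile(fileext = ".csv")
  write_proportions(p, f)
  ext2 <- register_external_proportions("file", f)
  expect_equal(ext2$proportions, p, tolerance = 1e-12)
})
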