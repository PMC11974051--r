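test_that("signatures sum upsampled cells per type", {
  # a type with a single cell: with-replacement sampling forces
  # signature row = cells_per_type * that cell's counts
  counts <- cbind(a1 = c(3L, 0L, 1L), b1 = c(0L, 2L, 5L), b2 = c(1L, 1L, 1L))
  rownames(counts) <- paste0("g", 1:3)
  ds <- cell_dataset(counts, c("A", "B", "B"))
  sig <- build_signature(ds, cells_per_type = 10000, seed = 1)
  expect_equal(unname(sig$values["A", ]), 10000 * c(3, 0, 1))
  expect_equal(dim(sig$values), c(2, 3))
  expect_false(sig$scaled)

  ds$type_names <- c("A", "B", "C")
  expect_error(build_signature(ds), "C")
})

test_that("cell-type removal enforces the 2-type floor and is reversible", {
  sc <- make_scenario(seed = 21, n_genes = 400, n_cells = 40, n_samples = 5,
                      markers_per_type = 20)
  sig <- sc$signature
  dep <- remove_cell_types(sig, c("type1", "type3", "type5"))
  expect_setequal(dep$type_names, c("type2", "type4"))
  expect_equal(dep$removed_types, c("type1", "type3", "type5"))
  expect_identical(dep$values, sig$values[c("type2", "type4"), ])

  expect_error(remove_cell_types(sig, paste0("type", 1:4)), "fewer than 2")

  # removing then re-adding the row reproduces the original exactly
  restored <- rbind(dep$values, sig$values[c("type1", "type3", "type5"), ])
  expect_identical(restored[sig$type_names, ], sig$values)

  r2 <- remove_cell_types(sig, n_random = 2, seed = 5)
  expect_equal(length(r2$type_names), 3)
  expect_identical(remove_cell_types(sig, n_random = 2, seed = 5)$type_names,
                   r2$type_names)
})

test_that("marker selection ranks by specificity with documented tie-breaks", {
  # disjoint support: each type's markers are exactly its nonzero genes
  values <- rbind(A = c(5, 2, 0, 0), B = c(0, 0, 7, 1))
  colnames(values) <- paste0("g", 1:4)
  sig <- structure(list(values = values, type_names = rownames(values),
                        gene_names = colnames(values), scaled = FALSE,
                        cells_per_type_used = 1L,
                        removed_types = character(0)),
                   class = "signature_matrix")
  mk <- select_marker_genes(sig, 2)
  expect_setequal(mk$per_type$A, c("g1", "g2"))
  expect_setequal(mk$per_type$B, c("g3", "g4"))
  expect_lte(length(mk$union), 2 * 2)

  # identical rows: all specificities tie at 1/2; expression then gene order
  tie <- sig
  tie$values <- rbind(A = c(1, 4, 4, 2), B = c(1, 4, 4, 2))
  colnames(tie$values) <- paste0("g", 1:4)
  mk2 <- select_marker_genes(tie, 2)
  # brute force: specificity all equal, expression ranks g2=g3 > g4 > g1,
  # g2 before g3 by gene order
  expect_equal(mk2$per_type$A, c("g2", "g3"))
  expect_equal(mk2$per_type$B, c("g2", "g3"))

  # invariant to global rescaling of the signature
  scaled10 <- sig
  scaled10$values <- sig$values * 10
  expect_identical(select_marker_genes(sig, 2)$per_type,
                   select_marker_genes(scaled10, 2)$per_type)

  expect_warning(select_marker_genes(sig, 10), "returning all")
  sigs <- sig
  sigs$scaled <- TRUE
  expect_error(select_marker_genes(sigs, 2), "unscaled")
})

test_that("clip + MinMax winsorises at the matrix percentile then rescales", {
  x <- matrix(0:100, nrow = 1)
  y <- clip_and_minmax(x, 95)
  # independent linear-interpolation percentile oracle on 0..100
  sorted <- sort(as.vector(x))
  h <- (length(sorted) - 1) * 0.95
  p95 <- sorted[floor(h) + 1] +
    (h - floor(h)) * (sorted[floor(h) + 2] - sorted[floor(h) + 1])
  expect_equal(p95, 95)
  expect_equal(max(y), 1)
  # the clipped top maps to 1 and the pre-clip p95 value also maps to 1
  expect_equal(y[1, 96], 1)
  expect_equal(min(y), 0)

  const <- matrix(3, 2, 2)
  expect_true(all(clip_and_minmax(const) == 0))

  # already-[0,1] data with no values above the percentile: idempotent
  z <- matrix(c(0, 0.2, 0.4, 1), 2, 2)
  expect_equal(clip_and_minmax(z, 100), z)

  set.seed(2)
  m <- matrix(rexp(200), 10, 20)
  s <- clip_and_minmax(m)
  expect_equal(range(s), c(0, 1))
  expect_error(clip_and_minmax(matrix(numeric(0), 0, 0)), "empty")
})
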