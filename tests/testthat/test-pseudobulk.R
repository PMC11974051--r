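test_that("random proportions are uniform draws normalised to the simplex", {
  p <- draw_random_proportions(50, 4, seed = 1)
  expect_true(all(p >= 0))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_identical(p, draw_random_proportions(50, 4, seed = 1))

  one <- draw_random_proportions(10, 1, seed = 2)
  expect_true(all(one == 1))
})

test_that("realistic proportions jitter a base composition with clipping", {
  base <- c(mac = 0.5, tc = 0.3, bc = 0.2)
  p0 <- draw_realistic_proportions(base, 5, noise_spec(proportion_sd = 0),
                                   seed = 3)
  expect_true(all(abs(sweep(p0, 2, base)) < 1e-12))

  p <- draw_realistic_proportions(base, 200, noise_spec(proportion_sd = 0.2),
                                  seed = 4)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= 0))

  # zero-clipping frequency agrees with an independent simulation using the
  # same documented draw policy (per-sample rnorm of length k, clip, renorm)
  base2 <- c(0.01, 0.99)
  p2 <- draw_realistic_proportions(base2, 1000,
                                   noise_spec(proportion_sd = 0.5), seed = 5)
  set.seed(5)
  zero_rows <- 0L
  for (i in 1:1000) {
    row <- pmax(base2 + rnorm(2, 0, 0.5), 0)
    while (sum(row) == 0) row <- pmax(base2 + rnorm(2, 0, 0.5), 0)
    if (any(row == 0)) zero_rows <- zero_rows + 1L
  }
  expect_equal(sum(apply(p2, 1, function(r) any(r == 0))), zero_rows)
  expect_gt(zero_rows, 0)

  expect_error(draw_realistic_proportions(c(0.5, 0.4), 5), "sum to 1")
})

test_that("cell allocation uses largest-remainder rounding to an exact total", {
  expect_equal(unname(proportions_to_counts(c(0.2, 0.3, 0.5), 5000)),
               c(1000L, 1500L, 2500L))
  expect_equal(unname(proportions_to_counts(c(1), 5000)), 5000L)

  # equal thirds: the two extra cells go to the first two types (tie by order)
  thirds <- proportions_to_counts(rep(1, 3) / 3, 5000)
  expect_equal(unname(thirds), c(1667L, 1667L, 1666L))

  # largest-remainder oracle by enumeration on random rows
  oracle <- function(row, total) {
    raw <- row * total
    counts <- floor(raw)
    left <- total - sum(counts)
    frac <- raw - counts
    while (left > 0) {
      i <- which(frac == max(frac))[1]
      counts[i] <- counts[i] + 1
      frac[i] <- -1
      left <- left - 1
    }
    as.integer(counts)
  }
  set.seed(6)
  for (i in 1:25) {
    row <- runif(sample(2:8, 1))
    row <- row / sum(row)
    total <- sample(c(7, 100, 5000), 1)
    got <- proportions_to_counts(row, total)
    expect_equal(unname(got), oracle(row, total))
    expect_equal(sum(got), total)
  }
})

test_that("pseudobulks conserve sampled counts and honour the cell budget", {
  # one type, unit counts everywhere: every gene's pseudobulk value = 5000
  counts <- matrix(1L, nrow = 4, ncol = 10,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  ds <- cell_dataset(counts, rep("only", 10))
  truth <- matrix(1, 1, 1, dimnames = list("b1", "only"))
  pb <- build_pseudobulks(ds, truth, 5000, seed = 7)
  expect_true(all(pb$expression == 5000))
  expect_false(pb$noise_applied)

  sc <- make_scenario(seed = 21, n_genes = 400, n_cells = 40, n_samples = 5,
                      markers_per_type = 20)
  pb1 <- build_pseudobulks(sc$dataset, sc$truth, 5000, seed = 8)
  pb2 <- build_pseudobulks(sc$dataset, sc$truth, 5000, seed = 8)
  expect_identical(pb1$expression, pb2$expression)

  bad <- sc$truth
  colnames(bad)[1] <- "adipocyte"
  expect_error(build_pseudobulks(sc$dataset, bad, 5000), "adipocyte")
})

test_that("bulk noise is seeded, non-negative and vanishes at zero settings", {
  sc <- make_scenario(seed = 21, n_genes = 400, n_cells = 40, n_samples = 5,
                      markers_per_type = 20)
  silent <- add_bulk_noise(sc$bulks, noise_spec(0, 0), seed = 9)
  expect_equal(silent$expression, sc$bulks$expression)
  expect_true(silent$noise_applied)

  noisy1 <- add_bulk_noise(sc$bulks, seed = 10)
  noisy2 <- add_bulk_noise(sc$bulks, seed = 10)
  expect_identical(noisy1$expression, noisy2$expression)
  expect_true(all(noisy1$expression >= 0))
  expect_false(identical(noisy1$expression, sc$bulks$expression))
})
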