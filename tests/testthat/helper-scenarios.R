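# Shared synthetic scenarios, memoised so several tests can reuse the same
# (deterministic) dataset without regenerating it.

.scenario_cache <- new.env(parent = emptyenv())

# Generate profiles, cells, ground truth, pseudobulks, signature and markers
# for one synthetic cohort.
make_scenario <- function(seed = 11, n_types = 5, n_genes = 2000,
                          n_cells = 500, n_samples = 100,
                          target_correlation = 0, total_cells = 5000,
                          markers_per_type = 150,
                          marker_block = min(200L, n_genes %/% (2L * n_types))) {
  key <- paste(seed, n_types, n_genes, n_cells, n_samples,
               target_correlation, total_cells, markers_per_type,
               marker_block, sep = "_")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  prof <- generate_cell_profiles(
    n_types, n_genes,
    similarity_spec(target_correlation,
                    n_marker_genes_per_type = marker_block),
    seed = seed)
  dataset <- sample_cells(prof, n_cells, seed = seed + 1)
  truth <- draw_random_proportions(n_samples, n_types, seed = seed + 2,
                                   type_names = prof$type_names)
  bulks <- build_pseudobulks(dataset, truth, total_cells, seed = seed + 3)
  signature <- build_signature(dataset, seed = seed + 4)
  markers <- select_marker_genes(signature, markers_per_type)
  sc <- list(profiles = prof, dataset = dataset, truth = truth,
             bulks = bulks, signature = signature, markers = markers)
  .scenario_cache[[key]] <- sc
  sc
}

# Deconvolve a scenario against its signature with the given types removed,
# returning evaluation metrics and (when types are missing) the NMF recovery.
run_recovery <- function(sc, missing_types = character(0), noisy = FALSE,
                         noise_seed = 99) {
  bulks <- sc$bulks
  if (noisy) bulks <- add_bulk_noise(bulks, seed = noise_seed)
  bs <- clip_and_minmax(bulks)
  sig <- sc$signature
  if (length(missing_types) > 0) sig <- remove_cell_types(sig, missing_types)
  ss <- clip_and_minmax(sig)
  dec <- nnls_deconvolve(bs, ss, sc$markers)
  ev <- evaluate_proportions(dec, sc$truth)
  out <- list(deconv = dec, evaluation = ev)
  if (length(missing_types) > 0) {
    res <- compute_residual(bs, reconstruct_bulks(dec, ss))
    fz <- factorize_residual(res, length(missing_types))
    rec <- match_factors(scale_factor_weights(fz),
                         sc$truth[, missing_types, drop = FALSE])
    out$residual <- res
    out$factorization <- fz
    out$recovery <- rec
  }
  out
}

# Hand-rolled scaled signature with fully disjoint support per type, for
# exact-mixture identities.
disjoint_signature <- function(n_types = 4, genes_per_type = 3) {
  n_genes <- n_types * genes_per_type
  values <- matrix(0, n_types, n_genes)
  for (t in seq_len(n_types)) {
    idx <- ((t - 1) * genes_per_type + 1):(t * genes_per_type)
    values[t, idx] <- seq(0.2, 1, length.out = genes_per_type)
  }
  dimnames(values) <- list(paste0("type", seq_len(n_types)),
                           sprintf("g%02d", seq_len(n_genes)))
  structure(
    list(values = values,
         type_names = rownames(values),
         gene_names = colnames(values),
         scaled = TRUE,
         cells_per_type_used = NA_integer_,
         removed_types = character(0)),
    class = "signature_matrix"
  )
}
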