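# Shared cohort construction for the numbered analysis scripts. Everything
# is seeded, so each script can rebuild the identical cohort cheaply instead
# of deserialising intermediate objects.

library(deconres)

main_cohort <- function(seed = 11L, n_types = 5, n_genes = 2000,
                        n_cells = 500, n_samples = 100,
                        target_correlation = 0, total_cells = 5000,
                        markers_per_type = 150) {
  profiles <- generate_cell_profiles(n_types, n_genes,
                                     similarity_spec(target_correlation),
                                     seed = seed)
  dataset <- sample_cells(profiles, n_cells, seed = seed + 1)
  truth <- draw_random_proportions(n_samples, n_types, seed = seed + 2,
                                   type_names = profiles$type_names)
  bulks <- build_pseudobulks(dataset, truth, total_cells, seed = seed + 3)
  signature <- build_signature(dataset, seed = seed + 4)
  markers <- select_marker_genes(signature, markers_per_type)
  list(profiles = profiles, dataset = dataset, truth = truth,
       bulks = bulks, signature = signature, markers = markers)
}

# Deconvolve a cohort, optionally with types removed from the reference and
# noise added to the bulks; returns deconvolution, evaluation and (when
# types are missing) the residual-NMF recovery.
deconvolve_cohort <- function(cohort, missing_types = character(0),
                              noisy = FALSE, noise_seed = 99L) {
  bulks <- cohort$bulks
  if (noisy) bulks <- add_bulk_noise(bulks, seed = noise_seed)
  bs <- clip_and_minmax(bulks)
  sig <- cohort$signature
  if (length(missing_types) > 0) sig <- remove_cell_types(sig, missing_types)
  ss <- clip_and_minmax(sig)
  dec <- nnls_deconvolve(bs, ss, cohort$markers)
  out <- list(deconv = dec, evaluation = evaluate_proportions(dec, cohort$truth),
              bulks_scaled = bs, signature_scaled = ss)
  if (length(missing_types) > 0) {
    res <- compute_residual(bs, reconstruct_bulks(dec, ss))
    fz <- factorize_residual(res, length(missing_types))
    out$residual <- res
    out$factorization <- fz
    out$recovery <- match_factors(scale_factor_weights(fz),
                                  cohort$truth[, missing_types, drop = FALSE])
  }
  out
}
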