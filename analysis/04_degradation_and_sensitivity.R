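#!/usr/bin/env Rscript
# Stage 4: how deconvolution and recovery degrade.
#
# (a) Degradation: pooled deconvolution r as 0-3 distinct types are removed
#     from the reference, averaged over 5 seeds.
# (b) Similarity sensitivity: best-match recovery r for a missing type when
#     the cell types are distinct (target correlation 0) versus similar
#     (0.8), on noisy bulks.
# (c) Noise sensitivity: best-match recovery r with and without default
#     bulk noise.
# Smaller cohorts (50 bulks, 300 cells/type) keep the 5-seed sweeps fast.

source(file.path("analysis", "helpers.R"))

dir.create("results", showWarnings = FALSE)

small <- function(seed, target = 0) {
  main_cohort(seed = seed, n_cells = 300, n_samples = 50,
              target_correlation = target)
}

# (a) degradation
deg <- do.call(rbind, lapply(0:3, function(m) {
  rs <- vapply(1:5, function(s) {
    cohort <- small(100 + s * 10)
    missing <- if (m > 0) paste0("type", seq_len(m)) else character(0)
    deconvolve_cohort(cohort, missing)$evaluation$pooled$r
  }, numeric(1))
  data.frame(n_missing = m, mean_pooled_r = mean(rs),
             min_r = min(rs), max_r = max(rs))
}))
write.csv(deg, file.path("results", "degradation.csv"), row.names = FALSE)
message("degradation (mean pooled r by #missing): ",
        paste(signif(deg$mean_pooled_r, 3), collapse = " -> "))

# (b) similarity sensitivity (noisy bulks in both arms)
sim_r <- function(target, s) {
  out <- deconvolve_cohort(small(200 + s * 10, target), "type5",
                           noisy = TRUE, noise_seed = 70 + s)
  mean(out$recovery$best_match$r)
}
similarity <- data.frame(
  target_correlation = c(0, 0.8),
  mean_best_r = c(mean(vapply(1:5, function(s) sim_r(0, s), numeric(1))),
                  mean(vapply(1:5, function(s) sim_r(0.8, s), numeric(1)))))
write.csv(similarity, file.path("results", "similarity_sensitivity.csv"),
          row.names = FALSE)
message("recovery r distinct vs similar types: ",
        paste(signif(similarity$mean_best_r, 3), collapse = " vs "))

# (c) noise sensitivity
noise_r <- function(noisy, s) {
  out <- deconvolve_cohort(small(300 + s * 10), "type5",
                           noisy = noisy, noise_seed = 999 + s)
  mean(out$recovery$best_match$r)
}
noise <- data.frame(
  bulks = c("noiseless", "noisy"),
  mean_best_r = c(mean(vapply(1:5, function(s) noise_r(FALSE, s), numeric(1))),
                  mean(vapply(1:5, function(s) noise_r(TRUE, s), numeric(1)))))
write.csv(noise, file.path("results", "noise_sensitivity.csv"),
          row.names = FALSE)
message("recovery r noiseless vs noisy bulks: ",
        paste(signif(noise$mean_best_r, 3), collapse = " vs "))
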