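#!/usr/bin/env Rscript
# Stage 1: simulate the main synthetic cohort.
#
# Five transcriptionally distinct cell types (target profile correlation 0),
# 500 sampled cells per type, and 100 pseudobulk samples of 5000 cells each
# with uniformly random mixing proportions. Writes the ground truth, the
# pseudobulk expression matrix, the per-type signature matrix and the
# selected marker genes to results/data/.

library(deconres)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 11L

profiles <- generate_cell_profiles(n_types = 5, n_genes = 2000,
                                   similarity = similarity_spec(0),
                                   seed = seed)
dataset <- sample_cells(profiles, n_cells_per_type = 500, seed = seed + 1)
truth <- draw_random_proportions(100, 5, seed = seed + 2,
                                 type_names = profiles$type_names)
bulks <- build_pseudobulks(dataset, truth, total_cells = 5000,
                           seed = seed + 3)
signature <- build_signature(dataset, seed = seed + 4)
markers <- select_marker_genes(signature, n_per_type = 150)

write_proportions(truth, file.path(out_dir, "truth.csv"))
write_bulk_matrix(bulks$expression, file.path(out_dir, "pseudobulks.tsv"))
write_bulk_matrix(signature$values, file.path(out_dir, "signature.tsv"))
write_gene_list(markers$union, file.path(out_dir, "marker_genes.txt"))

# summary table: realised pairwise similarity of the mean profiles
sim <- profile_similarity(profiles)
write.csv(round(sim, 4), file.path("results", "profile_similarity.csv"))

message("mean off-diagonal profile correlation: ",
        signif(mean(sim[upper.tri(sim)]), 3))
message("wrote cohort artifacts to ", out_dir)
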