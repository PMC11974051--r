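# End-to-end experiment orchestration: a validated configuration drives
# simulate -> pseudobulk -> reference -> deconvolve -> residual -> recover,
# every stage seeded from one master seed, with all artifacts and a
# digest-bearing manifest written to disk.

config_schema <- list(
  schema_version = "1",
  seed = 1L,
  n_types = 5L,
  n_genes = 2000L,
  n_cells_per_type = 500L,
  dispersion = 0.3,
  target_correlation = 0,
  n_marker_genes_per_type = 200L,
  baseline_expression = 0.5,
  marker_expression = 2,
  n_samples = 100L,
  total_cells = 5000L,
  proportions = "random",
  base_proportions = NULL,
  apply_noise = FALSE,
  libsize_sd = 0.1,
  gene_sd_frac = 0.05,
  proportion_sd = 0.05,
  cells_per_type_reference = 10000L,
  markers_per_type = 150L,
  clip_percentile = 95,
  remove_types = NULL,
  n_missing_random = NULL,
  rarity_threshold = NULL,
  rarity_mode = "any"
)

#' Build and validate an experiment configuration
#'
#' Starts from the documented defaults and overrides them with the supplied
#' values; unknown keys are rejected. The resulting object fully determines
#' an experiment run (see [run_experiment()]).
#'
#' @param ... Named overrides of the default configuration, or a single
#'   named list. Key names match the generator, pseudobulk, reference and
#'   recovery parameters (e.g. `seed`, `n_types`, `n_samples`,
#'   `total_cells`, `proportions = "random"|"realistic"`, `remove_types`,
#'   `n_missing_random`).
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(config_schema))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  config <- config_schema
  config[names(overrides)] <- overrides
  validate_config(config)
  structure(config, class = "experiment_config")
}

validate_config <- function(config) {
  required <- c("seed", "n_types", "n_genes", "n_samples", "total_cells",
                "proportions")
  missing <- required[vapply(config[required], is.null, TRUE)]
  if (length(missing) > 0) {
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "))
  }
  if (!config$proportions %in% c("random", "realistic")) {
    stop("proportions must be 'random' or 'realistic'")
  }
  if (config$proportions == "realistic" && is.null(config$base_proportions)) {
    stop("realistic proportions need base_proportions")
  }
  if (!is.null(config$remove_types) && !is.null(config$n_missing_random)) {
    stop("give at most one of remove_types and n_missing_random")
  }
  invisible(config)
}

# small deterministic string hash (not cryptographic), kept below 2^31
poly_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

file_digest <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 31 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

derive_seed <- function(master, stage) {
  (as.numeric(master) + poly_hash(stage)) %% 2147483647
}

#' Run a full missing-cell-type experiment from a configuration
#'
#' Executes the pipeline stages in dependency order: profile generation and
#' cell sampling, pseudobulk construction (with optional noise), full and
#' depleted signature building, marker selection, clip + MinMax scaling,
#' NNLS deconvolution against both references, residual computation against
#' the depleted reference, NMF recovery and factor-to-truth matching. Each
#' stage's random draws are seeded from the master seed plus a stage-name
#' hash, so inserting a stage does not perturb the others. All intermediate
#' artifacts are written under `out_dir` together with a manifest of file
#' digests.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory for artifacts (created if needed).
#' @return List with the in-memory results (`truth`, `deconv_full`,
#'   `deconv_depleted`, `evaluation_full`, `evaluation_depleted`,
#'   `residual`, `factorization`, `recovery`, `removed_types`) and the
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir = tempfile("experiment")) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- function(stage) derive_seed(config$seed, stage)

  profiles <- generate_cell_profiles(
    config$n_types, config$n_genes,
    similarity_spec(target_correlation = config$target_correlation,
                    n_marker_genes_per_type = config$n_marker_genes_per_type,
                    baseline_expression = config$baseline_expression,
                    marker_expression = config$marker_expression),
    seed = seeds("profiles")
  )
  dataset <- sample_cells(profiles, config$n_cells_per_type,
                          dispersion = config$dispersion,
                          seed = seeds("cells"))

  truth <- if (config$proportions == "random") {
    draw_random_proportions(config$n_samples, config$n_types,
                            seed = seeds("proportions"),
                            type_names = profiles$type_names)
  } else {
    base <- config$base_proportions
    names(base) <- profiles$type_names
    draw_realistic_proportions(base, config$n_samples,
                               noise_spec(proportion_sd = config$proportion_sd),
                               seed = seeds("proportions"))
  }
  bulks <- build_pseudobulks(dataset, truth, config$total_cells,
                             seed = seeds("pseudobulks"))
  if (isTRUE(config$apply_noise)) {
    bulks <- add_bulk_noise(bulks,
                            noise_spec(libsize_sd = config$libsize_sd,
                                       gene_sd_frac = config$gene_sd_frac),
                            seed = seeds("noise"))
  }

  signature <- build_signature(dataset, config$cells_per_type_reference,
                               seed = seeds("signature"))
  markers <- select_marker_genes(signature, config$markers_per_type)
  depleted <- signature
  if (!is.null(config$remove_types)) {
    depleted <- remove_cell_types(signature, config$remove_types)
  } else if (!is.null(config$n_missing_random) &&
             config$n_missing_random > 0) {
    depleted <- remove_cell_types(signature,
                                  n_random = config$n_missing_random,
                                  seed = seeds("removal"))
  }
  removed <- depleted$removed_types

  bulks_scaled <- clip_and_minmax(bulks, config$clip_percentile)
  sig_full_scaled <- clip_and_minmax(signature, config$clip_percentile)
  sig_dep_scaled <- clip_and_minmax(depleted, config$clip_percentile)

  deconv_full <- nnls_deconvolve(bulks_scaled, sig_full_scaled, markers)
  deconv_dep <- nnls_deconvolve(bulks_scaled, sig_dep_scaled, markers)
  eval_full <- evaluate_proportions(deconv_full, truth)
  eval_dep <- evaluate_proportions(deconv_dep, truth)

  residual <- compute_residual(bulks_scaled,
                               reconstruct_bulks(deconv_dep, sig_dep_scaled),
                               reference_tag = "depleted")
  factorization <- NULL
  recovery <- NULL
  if (length(removed) > 0) {
    factorization <- factorize_residual(residual, length(removed))
    scaled_w <- scale_factor_weights(factorization)
    idx <- seq_len(nrow(truth))
    if (!is.null(config$rarity_threshold)) {
      idx <- subset_by_rarity(truth, removed, config$rarity_threshold,
                              config$rarity_mode)
    }
    if (length(idx) > 1) {
      recovery <- match_factors(scaled_w[idx, , drop = FALSE],
                                truth[idx, removed, drop = FALSE],
                                proportions_mode = config$proportions)
    }
  }

  # artifacts
  write_counts(dataset, file.path(out_dir, "dataset"), format = "mtx")
  write_proportions(truth, file.path(out_dir, "truth.csv"))
  write_bulk_matrix(bulks$expression, file.path(out_dir, "pseudobulks.tsv"))
  write_bulk_matrix(signature$values, file.path(out_dir, "signature.tsv"))
  write_proportions(deconv_full$proportions,
                    file.path(out_dir, "proportions_full.csv"))
  write_proportions(deconv_dep$proportions,
                    file.path(out_dir, "proportions_depleted.csv"))
  write_bulk_matrix(residual$values, file.path(out_dir, "residual.tsv"))
  if (!is.null(factorization)) {
    write_bulk_matrix(factorization$sample_weights,
                      file.path(out_dir, "factor_weights.tsv"))
    write_bulk_matrix(factorization$gene_loadings,
                      file.path(out_dir, "factor_loadings.tsv"))
  }
  if (!is.null(recovery)) {
    grid <- as.data.frame(as.table(recovery$r_grid))
    names(grid) <- c("factor", "missing_type", "r")
    if (!is.null(recovery$rmse_grid)) {
      grid$rmse <- as.vector(recovery$rmse_grid)
    }
    write.csv(grid, file.path(out_dir, "recovery_grid.csv"),
              row.names = FALSE)
  }

  config_yaml <- yaml::as.yaml(config)
  writeLines(config_yaml, file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.yaml")
  manifest <- list(
    schema_version = config$schema_version,
    config_hash = sprintf("%08x", poly_hash(config_yaml)),
    package_version = as.character(utils::packageVersion("deconres")),
    stages = c("profiles", "cells", "proportions", "pseudobulks",
               "signature", "deconvolution", "residual", "recovery"),
    removed_types = as.list(removed),
    files = lapply(stats::setNames(files, files), function(f) {
      file_digest(file.path(out_dir, f))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  list(truth = truth,
       deconv_full = deconv_full,
       deconv_depleted = deconv_dep,
       evaluation_full = eval_full,
       evaluation_depleted = eval_dep,
       residual = residual,
       factorization = factorization,
       recovery = recovery,
       removed_types = removed,
       out_dir = out_dir,
       manifest = manifest)
}
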