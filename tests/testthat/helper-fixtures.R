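# small in-code fixtures shared across test files

# feature matrix with explicit values, samples in rows
fm_of <- function(values, layer = "SNP", meta = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  feature_matrix(values, layer = layer, feature_meta = meta)
}

random_fm <- function(n, m, seed = 1, layer = "SNP") {
  set.seed(seed)
  fm_of(matrix(rnorm(n * m), n, m), layer = layer)
}

# small simulated dataset reused by several files
small_sim <- function(seed = 1, ...) {
  defaults <- list(n_inbreds = 12, n_variants = 80, n_genes = 20,
                   n_metabolites = 6, seed = seed)
  cfg <- do.call(sim_config, utils::modifyList(defaults, list(...)))
  list(config = cfg, geno = simulate_genotypes(cfg))
}

# strong-linkage panel where GBLUP has a high, stable noiseless ceiling
panel_config <- function(n_inbreds = 22, seed = 1, ...) {
  sim_config(n_inbreds = n_inbreds, n_variants = 800, n_genes = 40,
             block_r = 0.95, n_environments = 7, reps_per_env = 2,
             seed = seed, ...)
}
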