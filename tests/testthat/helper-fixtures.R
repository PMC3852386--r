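# Shared fixtures, all built in code.

# Lazily cached default-condition simulations (one per seed), so several test
# files can reuse the same dataset without regenerating it.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(simulation_config(rng_seed = seed))
  .sim_cache[[key]]
}

.run_cache <- new.env(parent = emptyenv())
default_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- suppressMessages(suppressWarnings(
      run_pipeline(run_config(sim = default_sim(seed), rng_seed = seed))))
  .run_cache[[key]]
}

# tiny expression matrix: one row per feature, values given per time point
# and recycled over replicates, plus optional per-sample offsets
make_em <- function(values_by_tp, time_points = c(0, 2, 4, 12, 24),
                    n_rep = 2, noise = NULL, feature_ids = NULL) {
  stopifnot(is.matrix(values_by_tp))
  sample_time <- rep(time_points, each = n_rep)
  sample_rep <- rep(seq_len(n_rep), length(time_points))
  vals <- values_by_tp[, match(sample_time, time_points), drop = FALSE]
  if (!is.null(noise)) vals <- vals + noise
  rownames(vals) <- feature_ids %||%
    rownames(values_by_tp) %||% paste0("f", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("t%gh_rep%d", sample_time, sample_rep)
  expression_matrix(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal prediction table from an explicit pair list
make_predictions <- function(mirna_id, gene_id, n_sites = 1L) {
  n <- length(mirna_id)
  structure(data.frame(mirna_id = mirna_id, gene_id = gene_id,
                       n_sites = rep_len(n_sites, n),
                       best_site_type = rep_len("8mer", n),
                       source = rep_len("seed_scan", n),
                       stringsAsFactors = FALSE),
            class = c("prediction_table", "data.frame"))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
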