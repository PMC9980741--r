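# Shared fixtures: small matrices built in code, plus reduced-size cohort
# configurations used across test files.

tiny_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probe_ids %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a cohort small enough for per-test use but with the full planted structure
small_cohort <- function(seed = 1, n_cpgs = 800, ...) {
  simulate_cohort(simulation_config(n_cpgs = n_cpgs, seed = seed, ...))
}

# cohort with no planted structure at all (no blocks, no gradient, no batch)
null_cohort <- function(seed = 1, n_subjects = 120L,
                        cluster_sizes = c(30L, 30L, 30L, 30L), n_cpgs = 600) {
  simulate_cohort(simulation_config(
    n_subjects = n_subjects, cluster_sizes = cluster_sizes, n_cpgs = n_cpgs,
    case_flag_per_cluster = rep(0.5, 4), dmr_blocks = list(),
    global_effect_sd = 0, batch_effect_sd = 0, failed_probe_fraction = 0,
    missing_rate = 0, seed = seed))
}

# VAE settings sized for test runtime; the science is unchanged
test_vae_config <- function(...) {
  vae_config(hidden_sizes = c(64L, 32L), epochs = 120L, seed = 1L, ...)
}
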