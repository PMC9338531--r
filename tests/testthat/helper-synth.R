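# small default configs used across tests (kept light so the suite stays fast)

small_config <- function(seed = 1, ...) {
  args <- list(n_per_group = 10, n_genes = 400, n_pattern_genes = 5,
               n_events = 20, n_aberrant = 6, n_sf = 6,
               n_coupled_events = 6, n_hazard_events = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

step_net <- function(s) c(up = 1, down = -1, flat = 0)[s]

welch_p_rows <- function(a, b) {
  vapply(seq_len(nrow(a)),
         function(i) welch_t(a[i, ], b[i, ])$p_value, numeric(1))
}

# imputed log2 protein matrix of a simulated cohort
imputed_protein <- function(sim, k = 5) {
  m <- omics_matrix(sim$cohort$protein, "protein", log2 = TRUE)
  filter_and_impute(m, k_neighbors = k)$values
}
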