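# Small configurations keep the unit suite fast; the study-scale defaults are
# exercised in the acceptance tests.
small_cfg <- function(rng_seed = 11, ...) {
  sim_config(n_genes = 60, n_mirnas = 30, n_families = 12, top_k_families = 8,
             library_size = 3e5, rng_seed = rng_seed, ...)
}

small_design <- function(reps = 3) {
  tibble::tibble(
    sample = c(sprintf("low_%d", seq_len(reps)), sprintf("high_%d", seq_len(reps))),
    condition = rep(c("low", "high"), each = reps))
}

counts_tbl <- function(m, id = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), out)
}
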