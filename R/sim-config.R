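#' Simulation configuration
#'
#' Builds the configuration object consumed by every `simulate_*()` generator.
#' Defaults emulate the study design the pipeline is meant to analyse: two
#' growth densities (low, ~50% confluence vs high, overconfluent) with three
#' replicates each, negative-binomial counts with moderate biological
#' dispersion, a global ~1.75-fold rise of the miRNA pool at high density,
#' actinomycin-D decay time courses sampled at 0, 1, 2, 4, 8, 12, 18, 24, 36
#' and 48 h with three stable reference genes, and densitometry standard
#' curves calibrated so that planted AGO2 copy numbers reproduce the
#' nuclear:cytoplasmic shift (2:1 of ~70,000 copies/cell at low density,
#' 12:1 of ~88,000 at high density).
#'
#' @param n_genes number of simulated genes.
#' @param n_mirnas number of mature miRNAs.
#' @param n_families number of seed families (distinct nt 2-8 seeds).
#' @param n_replicates replicates per condition.
#' @param library_size expected reads per sample.
#' @param nb_dispersion NB dispersion phi in `var = mu + phi * mu^2`;
#'   0 gives Poisson counts.
#' @param frac_candidates fraction of genes planted as miRISC targets.
#' @param tx_effect_log2 planted transcriptional log2 fold change (applied to
#'   both exonic and intronic counts of candidates at high density).
#' @param ptx_effect_log2 planted post-transcriptional log2 fold change
#'   (applied to exonic counts only).
#' @param mirna_global_log2fc global log2 shift of all miRNAs at high density.
#' @param utr_length_nt 3'UTR length per gene.
#' @param top_k_families number of families treated as "abundant" and used for
#'   site planting.
#' @param decay_halflives_h tibble (gene, fraction, condition, t_half_h) of
#'   planted decay half-lives; `Inf` means stable.
#' @param reference_genes names of the stable qPCR reference genes.
#' @param timepoints_h actinomycin-D chase timepoints (hours).
#' @param ct_noise_sd replicate Ct noise standard deviation.
#' @param copies_per_cell tibble (fraction, condition, copies) of planted
#'   protein copy numbers.
#' @param cells_per_ul lysate cell density (cells per microlitre).
#' @param loaded_volume_ul lysate volume loaded per lane.
#' @param protein_molar_mass_g_per_mol molar mass of the quantified protein.
#'   Default 97,000 g/mol, a literature value for human AGO2; override for
#'   other proteins.
#' @param densitometry_slope standard-curve slope (intensity AU per ng).
#' @param densitometry_intercept standard-curve intercept (AU).
#' @param densitometry_noise_sd band-intensity noise SD (AU).
#' @param standard_masses_ng masses of the recombinant-protein dilution series.
#' @param rng_seed master integer seed; identical configurations produce
#'   byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_genes = 500,
                       n_mirnas = 60,
                       n_families = 25,
                       n_replicates = 3,
                       library_size = 2e6,
                       nb_dispersion = 0.05,
                       frac_candidates = 0.1,
                       tx_effect_log2 = 0.5,
                       ptx_effect_log2 = 1.5,
                       mirna_global_log2fc = log2(1.75),
                       utr_length_nt = 600,
                       top_k_families = 20,
                       decay_halflives_h = default_decay_halflives(),
                       reference_genes = c("HPRT1", "SNRNP200", "ZMYM4"),
                       timepoints_h = c(0, 1, 2, 4, 8, 12, 18, 24, 36, 48),
                       ct_noise_sd = 0.2,
                       copies_per_cell = default_copies_per_cell(),
                       cells_per_ul = 10000,
                       loaded_volume_ul = 10,
                       protein_molar_mass_g_per_mol = 97000,
                       densitometry_slope = 2000,
                       densitometry_intercept = 0,
                       densitometry_noise_sd = 0,
                       standard_masses_ng = c(0.25, 0.5, 1, 2, 4, 8),
                       rng_seed = 1L) {
  assert_count(n_genes, "n_genes", positive = FALSE)
  assert_count(n_mirnas, "n_mirnas")
  assert_count(n_families, "n_families")
  assert_count(n_replicates, "n_replicates")
  if (!is.numeric(library_size) || library_size <= 0) {
    abort("`library_size` must be positive")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    abort("`nb_dispersion` must be >= 0")
  }
  assert_fraction(frac_candidates, "frac_candidates")
  if (n_mirnas < n_families) abort("`n_mirnas` must be >= `n_families`")
  if (utr_length_nt < 50) abort("`utr_length_nt` must be >= 50")
  stopifnot(is.data.frame(decay_halflives_h),
            all(c("gene", "fraction", "condition", "t_half_h") %in%
                  names(decay_halflives_h)))
  if (any(decay_halflives_h$t_half_h <= 0)) {
    abort("planted half-lives must be positive (use Inf for stable genes)")
  }
  if (ct_noise_sd < 0) abort("`ct_noise_sd` must be >= 0")
  stopifnot(is.data.frame(copies_per_cell),
            all(c("fraction", "condition", "copies") %in% names(copies_per_cell)))
  cfg <- list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_families = as.integer(n_families), n_replicates = as.integer(n_replicates),
    library_size = library_size, nb_dispersion = nb_dispersion,
    frac_candidates = frac_candidates, tx_effect_log2 = tx_effect_log2,
    ptx_effect_log2 = ptx_effect_log2, mirna_global_log2fc = mirna_global_log2fc,
    utr_length_nt = as.integer(utr_length_nt),
    top_k_families = as.integer(min(top_k_families, n_families)),
    decay_halflives_h = as_tibble(decay_halflives_h),
    reference_genes = reference_genes,
    timepoints_h = timepoints_h, ct_noise_sd = ct_noise_sd,
    copies_per_cell = as_tibble(copies_per_cell),
    cells_per_ul = cells_per_ul, loaded_volume_ul = loaded_volume_ul,
    protein_molar_mass_g_per_mol = protein_molar_mass_g_per_mol,
    densitometry_slope = densitometry_slope,
    densitometry_intercept = densitometry_intercept,
    densitometry_noise_sd = densitometry_noise_sd,
    standard_masses_ng = standard_masses_ng,
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "sim_config")
}

#' Default planted decay half-lives
#'
#' Two miRISC-target genes whose cytoplasmic transcripts stabilise at high
#' density (6 h to 12 h), plus a short-lived nuclear pre-mRNA pool; reference
#' genes are added as stable (`Inf`) by [simulate_decay()].
#'
#' @return tibble with columns gene, fraction, condition, t_half_h.
#' @export
default_decay_halflives <- function() {
  tidyr::expand_grid(
    gene = c("TARGET1", "TARGET2"),
    fraction = c("cytoplasm", "nucleus"),
    condition = c("low", "high")
  ) |>
    mutate(t_half_h = dplyr::case_when(
      .data$fraction == "cytoplasm" & .data$condition == "low" ~ 6,
      .data$fraction == "cytoplasm" & .data$condition == "high" ~ 12,
      TRUE ~ 3
    ))
}

#' Default planted protein copies per cell
#'
#' Nuclear:cytoplasmic ratio 2:1 of a ~70,000-copy whole-cell pool at low
#' density and 12:1 of an ~88,000-copy pool at high density; whole-cell rows
#' are the exact compartment sums so the conservation check closes at zero
#' noise.
#'
#' @return tibble with columns fraction, condition, copies.
#' @export
default_copies_per_cell <- function() {
  tibble(
    fraction = rep(c("cytoplasm", "nucleus", "whole_cell"), 2),
    condition = rep(c("low", "high"), each = 3),
    copies = c(70000 / 3, 140000 / 3, 70000,
               88000 / 13, 88000 * 12 / 13, 88000)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d  miRNAs: %d in %d families  replicates: %d/condition\n",
              x$n_genes, x$n_mirnas, x$n_families, x$n_replicates))
  cat(sprintf("  library size: %g  NB dispersion: %g  candidates: %.0f%%\n",
              x$library_size, x$nb_dispersion, 100 * x$frac_candidates))
  cat(sprintf("  planted log2 effects: tx %.2f, post-tx %.2f; miRNA shift %.2f\n",
              x$tx_effect_log2, x$ptx_effect_log2, x$mirna_global_log2fc))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
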