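#' Simulate an actinomycin-D qPCR decay time course
#'
#' First-order decay expressed directly on the Ct scale: one halving of
#' template adds exactly one cycle, so `Ct(t) = Ct(0) + t / t_half` plus
#' replicate noise. Reference genes are emitted as stable (`t_half = Inf`,
#' flat in expectation) for every fraction and condition present in the
#' planted half-life table.
#'
#' @param cfg a [sim_config()]; `decay_halflives_h` supplies the planted
#'   half-lives and `timepoints_h` the sampling grid.
#' @return tibble (gene, fraction, condition, timepoint_h, replicate, ct).
#' @export
simulate_decay <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  hl <- cfg$decay_halflives_h
  if (any(hl$t_half_h <= 0)) abort("planted half-lives must be positive")
  withr::with_seed(sub_seed(cfg$rng_seed, 6L), {
    strata <- hl |> distinct(.data$fraction, .data$condition)
    refs <- tidyr::expand_grid(gene = cfg$reference_genes, strata) |>
      mutate(t_half_h = Inf)
    all_genes <- bind_rows(hl, refs)
    ct0 <- setNames(round(runif(length(unique(all_genes$gene)), 18, 24), 1),
                    unique(all_genes$gene))
    grid <- tidyr::expand_grid(
      all_genes,
      timepoint_h = cfg$timepoints_h,
      replicate = seq_len(cfg$n_replicates)
    )
    grid |>
      mutate(ct = unname(ct0[.data$gene]) + .data$timepoint_h / .data$t_half_h +
               rnorm(dplyr::n(), 0, cfg$ct_noise_sd)) |>
      select("gene", "fraction", "condition", "timepoint_h", "replicate", "ct")
  })
}

#' Simulate a densitometry standard curve and fraction intensities
#'
#' Band intensity is linear in loaded protein mass
#' (`intensity = slope * mass + intercept + noise`). Fraction intensities are
#' generated from the planted copies-per-cell ground truth via the loaded
#' cell number and the protein molar mass, so [copies_per_cell()] round-trips
#' exactly at zero noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `standards` (mass_ng, intensity_au), `samples`
#'   (fraction, condition, intensity_au) and the generating `params`.
#' @export
simulate_densitometry <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(sub_seed(cfg$rng_seed, 7L), {
    sl <- cfg$densitometry_slope; ic <- cfg$densitometry_intercept
    sd_ <- cfg$densitometry_noise_sd
    standards <- tibble(
      mass_ng = cfg$standard_masses_ng,
      intensity_au = sl * cfg$standard_masses_ng + ic +
        rnorm(length(cfg$standard_masses_ng), 0, sd_)
    )
    n_cells <- cfg$cells_per_ul * cfg$loaded_volume_ul
    samples <- cfg$copies_per_cell |>
      mutate(
        mass_ng = .data$copies * n_cells * cfg$protein_molar_mass_g_per_mol /
          AVOGADRO * 1e9,
        intensity_au = sl * .data$mass_ng + ic + rnorm(dplyr::n(), 0, sd_)
      ) |>
      select("fraction", "condition", "intensity_au")
    list(standards = standards, samples = samples,
         params = list(slope = sl, intercept = ic, noise_sd = sd_,
                       cells_per_ul = cfg$cells_per_ul,
                       loaded_volume_ul = cfg$loaded_volume_ul,
                       molar_mass = cfg$protein_molar_mass_g_per_mol))
  })
}

#' Simulate a complete dataset with planted ground truth
#'
#' Runs every generator in order (annotation, miRNome, ground truth, eCLIP
#' peaks with site planting, counts, decay, densitometry) under sub-seeds of
#' `cfg$rng_seed`. The same configuration always returns an identical
#' dataset.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: annotation, mirnome, truth, peaks,
#'   exonic/intronic/smallrna counts, design, ct_table, densitometry.
#' @export
simulate_dataset <- function(cfg) {
  annotation <- simulate_annotation(cfg)
  mirnome <- simulate_mirnome(cfg)
  truth <- make_ground_truth(cfg, annotation, mirnome)
  ec <- simulate_eclip_peaks(cfg, annotation, truth, mirnome)
  counts <- simulate_counts(cfg, annotation, ec$truth, mirnome)
  structure(
    list(cfg = cfg, annotation = ec$annotation, mirnome = mirnome,
         truth = ec$truth, peaks = ec$peaks,
         exonic = counts$exonic, intronic = counts$intronic,
         smallrna = counts$smallrna, design = counts$design,
         ct_table = simulate_decay(cfg),
         densitometry = simulate_densitometry(cfg)),
    class = "sim_dataset")
}
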