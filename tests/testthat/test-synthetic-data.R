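test_that("simulated annotation has introns, fixed UTRs and no overlaps", {
  cfg1 <- sim_config(n_genes = 1, n_mirnas = 4, n_families = 2, rng_seed = 7)
  ann1 <- simulate_annotation(cfg1)
  expect_equal(nrow(ann1$genes), 1L)
  expect_equal(nrow(ann1$introns), nrow(ann1$exons) - 1L)
  expect_error(simulate_annotation(sim_config(n_genes = 0, rng_seed = 7)),
               "empty annotation")

  ann <- simulate_annotation(sim_config(n_genes = 500, rng_seed = 9))
  expect_equal(nrow(ann$genes), 500L)
  # brute-force pairwise interval sweep
  g <- ann$genes[order(ann$genes$start), ]
  for (i in seq_len(nrow(g) - 1L)) {
    expect_true(g$end[i] <= g$start[i + 1L])
  }
  expect_true(all(ann$utrs$end - ann$utrs$start == 600L))
  expect_true(all(grepl("^[ACGT]+$", utr_sequences(ann))))
})

test_that("identical configurations produce byte-identical simulated files", {
  cfg <- small_cfg(rng_seed = 41)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("simulated miRNome respects family structure", {
  cfg <- sim_config(n_genes = 5, n_mirnas = 6, n_families = 3, rng_seed = 2)
  mn <- simulate_mirnome(cfg)
  expect_equal(length(unique(mn$mirnas$seed)), 3L)
  expect_true(all(nchar(mn$mirnas$sequence) %in% 20:24))
  expect_true(all(grepl("^[ACGU]+$", mn$mirnas$sequence)))
  # family assignment recomputed from sequences equals the planted one
  expect_equal(seed_of(mn$mirnas$sequence), mn$mirnas$seed)
  same <- simulate_mirnome(sim_config(n_genes = 5, n_mirnas = 3, n_families = 3,
                                      rng_seed = 2))
  expect_equal(length(unique(same$mirnas$seed)), 3L)
  expect_error(simulate_mirnome(sim_config(n_genes = 5, n_families = 0,
                                           rng_seed = 2)))
})

test_that("null effect sizes give exonic log2FC centered at zero", {
  cfg <- sim_config(n_genes = 400, n_mirnas = 10, n_families = 5,
                    tx_effect_log2 = 0, ptx_effect_log2 = 0,
                    library_size = 1e6, rng_seed = 19)
  sim <- simulate_dataset(cfg)
  m <- miriscshift:::counts_to_matrix(sim$exonic)
  lfc <- log2(rowMeans(m[, 4:6]) + 0.5) - log2(rowMeans(m[, 1:3]) + 0.5)
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc)), 3 * se)
})

test_that("zero dispersion gives Poisson counts (variance tracks the mean)", {
  ratios <- purrr::map_dbl(1:50, function(s) {
    cfg <- sim_config(n_genes = 50, n_mirnas = 6, n_families = 3,
                      nb_dispersion = 0, frac_candidates = 0,
                      library_size = 5e4, rng_seed = 1000 + s)
    ann <- simulate_annotation(cfg)
    mir <- simulate_mirnome(cfg)
    truth <- make_ground_truth(cfg, ann, mir)
    m <- miriscshift:::counts_to_matrix(
      simulate_counts(cfg, ann, truth, mir)$exonic)
    low <- m[, 1:3]
    mean(apply(low, 1, var)) / mean(rowMeans(low))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("planted post-transcriptional effect shows up as the exon/intron ratio", {
  # Monte-Carlo over replicate simulations: the ratio of exonic to intronic
  # high/low fold changes of candidate genes converges to 2^ptx
  cfg0 <- sim_config(n_genes = 40, n_mirnas = 6, n_families = 3,
                     frac_candidates = 0.25, tx_effect_log2 = 0.5,
                     ptx_effect_log2 = 1.5, library_size = 2e5, rng_seed = 1)
  ann <- simulate_annotation(cfg0)
  mir <- simulate_mirnome(cfg0)
  truth <- make_ground_truth(cfg0, ann, mir)
  cand <- truth$candidates
  rats <- purrr::map_dbl(1:200, function(s) {
    cfg <- sim_config(n_genes = 40, n_mirnas = 6, n_families = 3,
                      frac_candidates = 0.25, tx_effect_log2 = 0.5,
                      ptx_effect_log2 = 1.5, library_size = 2e5,
                      rng_seed = 5000 + s)
    cnt <- simulate_counts(cfg, ann, truth, mir)
    ex <- miriscshift:::counts_to_matrix(cnt$exonic)[cand, , drop = FALSE]
    inr <- miriscshift:::counts_to_matrix(cnt$intronic)[cand, , drop = FALSE]
    (mean(ex[, 4:6]) / mean(ex[, 1:3])) / (mean(inr[, 4:6]) / mean(inr[, 1:3]))
  })
  expect_equal(mean(rats), 2^1.5, tolerance = 0.08)
  expect_error(simulate_counts(
    sim_config(n_genes = 5, library_size = -1, rng_seed = 1), ann, truth, mir))
})

test_that("eCLIP planting is exactly recoverable and decoys are clean", {
  cfg <- small_cfg(rng_seed = 47)
  sim <- simulate_dataset(cfg)
  # every planted peak lies within its gene's UTR (transcript frame)
  expect_true(all(sim$truth$planted_sites$utr_start >= 0))
  expect_true(all(sim$truth$planted_sites$utr_end <= cfg$utr_length_nt))
  # cross-module: scanning recovers at least the planted site count per gene
  fam <- group_families(sim$mirnome$mirnas, sim$smallrna, design = sim$design,
                        top_k = cfg$top_k_families)
  ann <- annotate_peaks(sim$peaks, sim$annotation, fam)
  tal <- count_utr_sites(ann)
  planted_per_gene <- sim$truth$planted_sites |>
    dplyr::filter(.data$gene_id %in% sim$truth$candidates) |>
    dplyr::count(.data$gene_id)
  for (i in seq_len(nrow(planted_per_gene))) {
    got <- tal$n_utr_sites[tal$gene_id == planted_per_gene$gene_id[i]]
    expect_gte(got, 1L)
  }
  # no candidates -> no qualifying cytoplasmic UTR sites anywhere
  sim0 <- simulate_dataset(small_cfg(rng_seed = 48, frac_candidates = 0))
  fam0 <- group_families(sim0$mirnome$mirnas, sim0$smallrna,
                         design = sim0$design, top_k = cfg$top_k_families)
  tal0 <- count_utr_sites(annotate_peaks(sim0$peaks, sim0$annotation, fam0))
  expect_equal(nrow(tal0), 0L)
})

test_that("simulated decay follows one-Ct-per-halving and round-trips", {
  hl <- tibble::tibble(gene = "T1", fraction = "cytoplasm", condition = "low",
                       t_half_h = 8)
  cfg <- sim_config(n_genes = 5, decay_halflives_h = hl, ct_noise_sd = 0,
                    timepoints_h = c(0, 8, 16, 24), rng_seed = 3)
  ct <- simulate_decay(cfg)
  t1 <- ct |> dplyr::filter(gene == "T1", replicate == 1)
  expect_equal(t1$ct[t1$timepoint_h == 8] - t1$ct[t1$timepoint_h == 0], 1.0)
  refs <- ct |> dplyr::filter(gene == "HPRT1")
  expect_equal(length(unique(refs$ct)), 1L)  # flat at zero noise
  fits <- fit_halflives(ct)
  expect_equal(fits$t_half_h[fits$gene == "T1"], 8, tolerance = 1e-9)
  expect_error(sim_config(n_genes = 5, decay_halflives_h =
    dplyr::mutate(hl, t_half_h = -1)), "positive")
})

test_that("stable transcripts give a flat series flagged as stable", {
  hl <- tibble::tibble(gene = "T1", fraction = "cytoplasm", condition = "low",
                       t_half_h = Inf)
  cfg <- sim_config(n_genes = 5, decay_halflives_h = hl, ct_noise_sd = 0,
                    rng_seed = 3)
  ct <- simulate_decay(cfg)
  expect_equal(length(unique(ct$ct[ct$gene == "T1"])), 1L)
  fits <- fit_halflives(ct)
  expect_true(all(fits$flag == "stable"))
  expect_true(all(is.infinite(fits$t_half_h)))
})

test_that("noise-free densitometry round-trips slope and copies", {
  cfg <- sim_config(n_genes = 5, densitometry_noise_sd = 0, rng_seed = 13)
  dn <- simulate_densitometry(cfg)
  curve <- fit_standard_curve(dn$standards)
  expect_equal(curve$slope, cfg$densitometry_slope, tolerance = 1e-12)
  est <- copies_per_cell(dn$samples$intensity_au, curve,
                         cells_per_ul = cfg$cells_per_ul,
                         loaded_volume_ul = cfg$loaded_volume_ul,
                         molar_mass_g_per_mol = cfg$protein_molar_mass_g_per_mol)
  expect_equal(est$copies_per_cell, cfg$copies_per_cell$copies,
               tolerance = 0.01)
  # doubling the loaded volume doubles the (background-free) intensity
  cfg2 <- sim_config(n_genes = 5, densitometry_noise_sd = 0,
                     loaded_volume_ul = 2 * cfg$loaded_volume_ul, rng_seed = 13)
  dn2 <- simulate_densitometry(cfg2)
  expect_equal(dn2$samples$intensity_au, 2 * dn$samples$intensity_au)
})
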