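#' Simulate a mature miRNome organized in seed families
#'
#' Draws `n_families` distinct nt 2-8 seeds and distributes `n_mirnas`
#' members over them (every family gets at least one). Members of a family
#' share the seed exactly; position 1 and the 3' tail are random, giving
#' mature lengths of 20-24 nt. Families are assigned geometrically decaying
#' baseline abundances so that the designated top `top_k_families` are
#' unambiguously the most expressed — the ground truth for "top 20 most
#' abundant families" selection.
#'
#' @param cfg a [sim_config()].
#' @return list with `mirnas` (tibble: name, sequence, family_id, seed) and
#'   `families` (tibble: family_id, family_seed, weight, is_top).
#' @export
simulate_mirnome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families == 0L) abort("n_families must be positive")
  withr::with_seed(sub_seed(cfg$rng_seed, 2L), {
    rna <- c("A", "C", "G", "U")
    seeds <- character(0)
    while (length(seeds) < cfg$n_families) {
      cand <- paste(sample(rna, 7, replace = TRUE), collapse = "")
      if (!cand %in% seeds) seeds <- c(seeds, cand)
    }
    fam_of <- c(seq_len(cfg$n_families),
                sample(cfg$n_families, cfg$n_mirnas - cfg$n_families,
                       replace = TRUE))
    fam_of <- sort(fam_of)
    mirnas <- map(seq_len(cfg$n_mirnas), function(i) {
      fam <- fam_of[i]
      len <- sample(20:24, 1)
      seq <- paste0(sample(rna, 1),
                    seeds[fam],
                    paste(sample(rna, len - 8, replace = TRUE), collapse = ""))
      tibble(name = sprintf("sim-miR-%02d%s", fam,
                            letters[sum(fam_of[seq_len(i)] == fam)]),
             sequence = seq, family_id = fam, seed = seeds[fam])
    }) |> bind_rows()
    # steep abundance ladder: top families separated by clear margins
    weight <- 2e4 * 0.8^(seq_len(cfg$n_families) - 1)
    weight[seq_len(cfg$n_families) > cfg$top_k_families] <- 5
    families <- tibble(
      family_id = seq_len(cfg$n_families), family_seed = seeds,
      weight = weight, is_top = seq_len(cfg$n_families) <= cfg$top_k_families
    )
    list(mirnas = mirnas, families = families)
  })
}

#' Plant the ground truth for a simulated dataset
#'
#' Chooses which genes are miRISC candidates and records their planted
#' transcriptional and post-transcriptional effects. Peaks and sites are
#' appended by [simulate_eclip_peaks()].
#'
#' @param cfg a [sim_config()].
#' @param annotation a [simulate_annotation()] result.
#' @param mirnome a [simulate_mirnome()] result.
#' @return list of class `sim_truth` with `candidates`, `effects` (tibble:
#'   gene_id, tx_log2, ptx_log2), planted decay half-lives and protein
#'   copies.
#' @export
make_ground_truth <- function(cfg, annotation, mirnome) {
  withr::with_seed(sub_seed(cfg$rng_seed, 3L), {
    n_cand <- round(cfg$frac_candidates * cfg$n_genes)
    candidates <- sort(sample(annotation$genes$gene_id, n_cand))
    effects <- tibble(
      gene_id = annotation$genes$gene_id,
      is_candidate = annotation$genes$gene_id %in% candidates,
      tx_log2 = if_else(annotation$genes$gene_id %in% candidates,
                        cfg$tx_effect_log2, 0),
      ptx_log2 = if_else(annotation$genes$gene_id %in% candidates,
                         cfg$ptx_effect_log2, 0)
    )
    structure(
      list(candidates = candidates, effects = effects,
           halflives = cfg$decay_halflives_h,
           copies_per_cell = cfg$copies_per_cell,
           top_family_seeds = mirnome$families$family_seed[mirnome$families$is_top]),
      class = "sim_truth")
  })
}
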