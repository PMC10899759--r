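#' Pipeline configuration
#'
#' Collects every threshold of the candidate-refinement analysis. Defaults
#' follow the study design: post-transcriptional calls at EISA FDR < 0.001,
#' "upregulated" DE candidates at log2FC > 0 and FDR < 0.05 (the DE cutoff
#' is not pinned by the study and is fully configurable), top 20 seed
#' families ranked at high density, cytoplasmic 3'UTR peaks, and all three
#' strong site types.
#'
#' @param simulate generate inputs with [simulate_dataset()]? When `FALSE`,
#'   `paths` must name gff3, genome_fa, peaks_bed, mirna_fa, exonic, intronic,
#'   smallrna, design, ct, densitometry_standards, densitometry_fractions.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param paths named list of input file paths (file mode).
#' @param top_k_families families counted as abundant.
#' @param de_fdr FDR cutoff for "upregulated" DE candidates.
#' @param eisa_fdr FDR cutoff for post-transcriptional calls.
#' @param site_types qualifying seed-site types.
#' @param compartment qualifying peak compartment.
#' @param region qualifying peak region.
#' @param min_log2_mean EISA abundance filter.
#' @param rank_condition condition whose samples rank family abundance.
#' @param condition_a,condition_b baseline and contrast conditions.
#' @param reference_genes qPCR reference genes.
#' @param rng_seed master seed (simulation mode).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(rng_seed = rng_seed),
                            paths = NULL,
                            top_k_families = 20, de_fdr = 0.05, eisa_fdr = 0.001,
                            site_types = c("8mer", "7mer-m8", "7mer-A1"),
                            compartment = "cytoplasm",
                            region = "three_prime_utr",
                            min_log2_mean = 5, rank_condition = "high",
                            condition_a = "low", condition_b = "high",
                            reference_genes = c("HPRT1", "SNRNP200", "ZMYM4"),
                            rng_seed = 1L) {
  for (thr in list(de_fdr = de_fdr, eisa_fdr = eisa_fdr)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1) {
      abort("FDR thresholds must lie in (0, 1]")
    }
  }
  structure(
    list(simulate = simulate, sim = sim, paths = paths,
         top_k_families = top_k_families, de_fdr = de_fdr, eisa_fdr = eisa_fdr,
         site_types = site_types, compartment = compartment, region = region,
         min_log2_mean = min_log2_mean, rank_condition = rank_condition,
         condition_a = condition_a, condition_b = condition_b,
         reference_genes = reference_genes, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param yaml_path YAML file whose keys mirror [pipeline_config()]
#'   arguments; a `sim:` block is passed to [sim_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(yaml_path) {
  y <- yaml::read_yaml(yaml_path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Refine miRISC candidate targets
#'
#' The core candidate-refinement filter: keep genes with at least one peak in
#' the required compartment and region containing at least one qualifying
#' seed site of a top-ranked family, then annotate differential-expression
#' status. Candidates are ranked by site count (descending), then log2FC
#' (descending), then gene id.
#'
#' @param annotated output of [annotate_peaks()].
#' @param families output of [group_families()].
#' @param de a [nb_exact_test()] result.
#' @param cfg a [pipeline_config()] (thresholds and filters).
#' @return tibble of class `candidate_targets`: gene, n_utr_peaks,
#'   n_utr_sites, families, log2fc, fdr, upregulated, rank.
#' @export
refine_candidates <- function(annotated, families, de, cfg = pipeline_config()) {
  tally <- count_utr_sites(annotated, site_types = cfg$site_types,
                           compartment = cfg$compartment)
  peak_genes <- unique(annotated$peaks$gene_id)
  if (!length(intersect(peak_genes, de$gene))) {
    abort("gene universes of peaks and DE results do not intersect; check that inputs share gene ids")
  }
  out <- tally |>
    left_join(de |> select("gene", "log2fc", "fdr"),
              by = c(gene_id = "gene")) |>
    mutate(upregulated = !is.na(.data$log2fc) &
             .data$log2fc > 0 & .data$fdr < cfg$de_fdr) |>
    arrange(desc(.data$n_utr_sites), desc(.data$log2fc), .data$gene_id) |>
    mutate(rank = row_number())
  class(out) <- c("candidate_targets", class(out))
  out
}

#' Attach EISA classes to candidate targets
#'
#' Left-joins the classified EISA results; candidates that EISA filtered out
#' (e.g. below the abundance filter) are flagged `untested`.
#'
#' @param candidates a [refine_candidates()] result.
#' @param eisa_result a [classify_regulation()] result.
#' @return candidates with `eisa_class` and `d_diff` columns.
#' @export
attach_eisa <- function(candidates, eisa_result) {
  out <- candidates |>
    left_join(eisa_result |> select("gene", "d_diff", eisa_class = "class"),
              by = c(gene_id = "gene")) |>
    mutate(eisa_class = dplyr::coalesce(.data$eisa_class, "untested"))
  class(out) <- class(candidates)
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full candidate-refinement pipeline
#'
#' Executes simulate (or load) -> normalize -> differential expression ->
#' seed-family ranking -> peak annotation -> candidate refinement -> EISA ->
#' half-life fitting -> absolute quantitation, writes every result table,
#' a JSON provenance block and a plain-text summary to `outdir`, and returns
#' the results invisibly. Output bytes are a pure function of the
#' configuration.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param outdir output directory.
#' @return invisibly, a list with every stage result.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail_clean <- function(expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(e)
    })
  }
  on_fail_clean({
    if (isTRUE(config$simulate)) {
      sim <- run_stage("simulate", simulate_dataset(config$sim))
      annotation <- sim$annotation; peaks <- sim$peaks
      mirnas <- sim$mirnome$mirnas
      exonic <- sim$exonic; intronic <- sim$intronic
      smallrna <- sim$smallrna; design <- sim$design
      ct_table <- sim$ct_table
      dens_std <- sim$densitometry$standards
      dens_smp <- sim$densitometry$samples
      dens_par <- sim$densitometry$params
    } else {
      p <- config$paths
      sim <- NULL
      annotation <- run_stage("load", read_annotation_gff3(p$gff3, p$genome_fa))
      peaks <- run_stage("load", read_peaks_bed(p$peaks_bed))
      mir_seqs <- run_stage("load", read_fasta_seqs(p$mirna_fa, "RNA"))
      mirnas <- tibble(name = names(mir_seqs), sequence = unname(mir_seqs))
      exonic <- run_stage("load", read_counts_tsv(p$exonic))
      intronic <- run_stage("load", read_counts_tsv(p$intronic))
      smallrna <- run_stage("load", read_counts_tsv(p$smallrna))
      design <- run_stage("load", read_counts_tsv(p$design))
      ct_table <- run_stage("load", read_counts_tsv(p$ct))
      dens_std <- run_stage("load", read_counts_tsv(p$densitometry_standards))
      dens_smp <- run_stage("load", read_counts_tsv(p$densitometry_fractions))
      dens_par <- list(cells_per_ul = 10000, loaded_volume_ul = 10,
                       molar_mass = 97000)
    }
    families <- run_stage("families", group_families(
      mirnas, smallrna, design = design,
      rank_condition = config$rank_condition, top_k = config$top_k_families))
    de <- run_stage("de", nb_exact_test(
      exonic, design, config$condition_a, config$condition_b))
    annotated <- run_stage("scan", annotate_peaks(peaks, annotation, families))
    candidates <- run_stage("refine", refine_candidates(
      annotated, families, de, config))
    eisa_res <- run_stage("eisa", {
      r <- eisa(exonic, intronic, design, config$condition_a,
                config$condition_b, min_log2_mean = config$min_log2_mean)
      classify_regulation(r, fdr_threshold = config$eisa_fdr)
    })
    candidates <- run_stage("refine", attach_eisa(candidates, eisa_res))
    halflives <- run_stage("halflife", fit_halflives(
      ct_table, reference_genes = config$reference_genes))
    quant <- run_stage("quant", {
      curve <- fit_standard_curve(dens_std)
      est <- dens_smp |>
        bind_cols(copies_per_cell(
          dens_smp$intensity_au, curve,
          cells_per_ul = dens_par$cells_per_ul,
          loaded_volume_ul = dens_par$loaded_volume_ul,
          molar_mass_g_per_mol = dens_par$molar_mass) |>
            select("mass_ng", "copies_per_cell", "flag"))
      ratios <- est |>
        group_by(.data$condition) |>
        summarise(ratio = {
          n <- .data$copies_per_cell[.data$fraction == "nucleus"]
          c_ <- .data$copies_per_cell[.data$fraction == "cytoplasm"]
          if (length(n) && length(c_)) n[1] / c_[1] else NA_real_
        }, .groups = "drop")
      list(curve = curve, estimates = est, ratios = ratios)
    })

    path <- function(f) { p <- file.path(outdir, f); written <<- c(written, p); p }
    readr::write_tsv(candidates |> mutate(families = map_chr(
      .data$families, paste, collapse = ";")), path("candidates.tsv"))
    readr::write_tsv(as_tibble(eisa_res), path("eisa.tsv"))
    readr::write_tsv(as_tibble(de), path("de.tsv"))
    readr::write_tsv(annotated$sites, path("sites.tsv"))
    readr::write_tsv(families |> select(-"cpm", -"members") |>
                       bind_cols(tibble(members = map_chr(
                         families$members, paste, collapse = ";"))),
                     path("families.tsv"))
    readr::write_tsv(halflives, path("halflife.tsv"))
    readr::write_tsv(quant$estimates, path("quant.tsv"))
    prov <- list(
      package = "miriscshift",
      version = as.character(utils::packageVersion("miriscshift")),
      config_hash = rlang::hash(config),
      rng_seed = config$rng_seed,
      thresholds = list(top_k_families = config$top_k_families,
                        de_fdr = config$de_fdr, eisa_fdr = config$eisa_fdr,
                        min_log2_mean = config$min_log2_mean),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
    jsonlite::write_json(prov, path("provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    report <- c(
      "miRISC candidate refinement summary",
      sprintf("genes tested (DE): %d", nrow(de)),
      sprintf("top families used: %d", sum(families$top_family)),
      sprintf("candidate targets: %d", nrow(candidates)),
      sprintf("  upregulated (log2FC > 0, FDR < %g): %d",
              config$de_fdr, sum(candidates$upregulated)),
      sprintf("  post-transcriptional by EISA (FDR < %g): %d",
              config$eisa_fdr,
              sum(candidates$eisa_class == "post_transcriptional")),
      sprintf("half-life fits: %d (%d estimable)",
              nrow(halflives), sum(halflives$flag == "ok")),
      sprintf("nuclear:cytoplasmic copy ratios: %s",
              paste(sprintf("%s=%.2f", quant$ratios$condition,
                            quant$ratios$ratio), collapse = ", ")))
    writeLines(report, path("report.txt"))
    invisible(list(config = config, sim = sim, families = families, de = de,
                   annotated = annotated, candidates = candidates,
                   eisa = eisa_res, halflives = halflives, quant = quant,
                   report = report))
  })
}
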