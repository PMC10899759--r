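#' Simulate AGO2-eCLIP peaks with planted seed sites
#'
#' Every candidate gene receives 1-3 cytoplasmic peaks inside its 3'UTR,
#' each with one or two seed-match sites for a top-abundance family written
#' into the UTR sequence (site type drawn from 8mer / 7mer-m8 / 7mer-A1).
#' Decoy peaks are also emitted: nuclear 3'UTR peaks (some with planted
#' sites, to exercise the compartment filter), cytoplasmic intronic peaks,
#' and cytoplasmic 3'UTR peaks on non-candidate genes whose footprints are
#' scrubbed of any top-family site, so the planted candidate set is exactly
#' recoverable.
#'
#' @param cfg a [sim_config()].
#' @param annotation a [simulate_annotation()] result; its genome is edited
#'   and the modified annotation is returned.
#' @param truth a [make_ground_truth()] result; planted peak/site records
#'   are appended.
#' @param mirnome a [simulate_mirnome()] result.
#' @return list with `peaks` (tibble: chrom, start, end, gene_id, score,
#'   strand, compartment), the modified `annotation`, and `truth` with
#'   `planted_sites` (tibble: gene_id, utr_start, utr_end, site_type,
#'   family_seed) attached.
#' @export
simulate_eclip_peaks <- function(cfg, annotation, truth, mirnome) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  utr_len <- cfg$utr_length_nt
  withr::with_seed(sub_seed(cfg$rng_seed, 5L), {
    useqs <- utr_sequences(annotation)
    top_seeds <- mirnome$families$family_seed[mirnome$families$is_top]
    top_pats <- unlist(map(top_seeds, function(s) unlist(site_patterns(s))))
    peaks <- list()
    planted <- list()
    add_peak <- function(gene_id, utr_s, utr_e, compartment) {
      u <- annotation$utrs[annotation$utrs$gene_id == gene_id, ]
      if (u$strand == "+") {
        gs <- u$start + utr_s; ge <- u$start + utr_e
      } else {
        gs <- u$end - utr_e; ge <- u$end - utr_s
      }
      peaks[[length(peaks) + 1L]] <<- tibble(
        chrom = u$chrom, start = gs, end = ge, gene_id = gene_id,
        score = 0L, strand = u$strand, compartment = compartment)
    }
    plant_site <- function(gene_id, pos, pattern, type, seed) {
      s <- useqs[[gene_id]]
      substr(s, pos + 1L, pos + nchar(pattern)) <- pattern
      useqs[[gene_id]] <<- s
      planted[[length(planted) + 1L]] <<- tibble(
        gene_id = gene_id, utr_start = pos, utr_end = pos + nchar(pattern),
        site_type = type, family_seed = seed)
    }
    for (g in truth$candidates) {
      n_pk <- sample(1:3, 1)
      if (n_pk * 80 > utr_len) n_pk <- max(1L, utr_len %/% 80)
      # non-overlapping peak slots across the UTR
      slot <- floor(utr_len / n_pk)
      for (k in seq_len(n_pk)) {
        width <- sample(40:min(70, slot - 4), 1)
        ps <- (k - 1L) * slot + sample.int(slot - width - 2L, 1)
        n_sites <- sample(1:2, 1)
        fam <- sample(top_seeds, n_sites, replace = length(top_seeds) < n_sites)
        type <- sample(c("8mer", "7mer-m8", "7mer-A1"), n_sites, replace = TRUE)
        offs <- ps + 2L + (seq_len(n_sites) - 1L) * 12L
        for (j in seq_len(n_sites)) {
          pat <- site_patterns(fam[j])[[type[j]]]
          plant_site(g, offs[j], pat, type[j], fam[j])
        }
        add_peak(g, ps, ps + width, "cytoplasm")
      }
    }
    non_cand <- setdiff(annotation$genes$gene_id, truth$candidates)
    # nuclear UTR decoys, some with a genuine planted site
    n_nuc <- min(length(non_cand), max(2L, length(truth$candidates)))
    for (g in head(non_cand, n_nuc)) {
      width <- sample(40:min(70, utr_len - 10L), 1)
      ps <- sample.int(utr_len - width - 2L, 1)
      if (runif(1) < 0.5) {
        fam <- sample(top_seeds, 1)
        plant_site(g, ps + 2L, site_patterns(fam)[["8mer"]], "8mer", fam)
      }
      add_peak(g, ps, ps + width, "nucleus")
    }
    # cytoplasmic UTR decoys without sites, footprints scrubbed below
    scrub_targets <- list()
    n_cyt <- min(length(non_cand), max(2L, length(truth$candidates) %/% 2L))
    for (g in tail(non_cand, n_cyt)) {
      width <- sample(40:min(70, utr_len - 10L), 1)
      ps <- sample.int(utr_len - width - 2L, 1)
      add_peak(g, ps, ps + width, "cytoplasm")
      scrub_targets[[length(scrub_targets) + 1L]] <- list(gene = g, s = ps, e = ps + width)
    }
    # cytoplasmic intronic decoys
    for (g in sample(annotation$genes$gene_id, min(cfg$n_genes, 10L))) {
      intr <- annotation$introns[annotation$introns$gene_id == g, ]
      if (!nrow(intr)) next
      iv <- intr[sample.int(nrow(intr), 1), ]
      width <- min(50L, iv$end - iv$start - 2L)
      peaks[[length(peaks) + 1L]] <- tibble(
        chrom = iv$chrom, start = iv$start + 1L, end = iv$start + 1L + width,
        gene_id = g, score = 0L, strand = iv$strand, compartment = "cytoplasm")
    }
    # scrub decoy cytoplasmic UTR footprints of every top-family pattern
    for (tg in scrub_targets) {
      useqs[[tg$gene]] <- scrub_patterns(useqs[[tg$gene]], top_pats, tg$s, tg$e)
    }
    # write edited UTRs back into the genome (strand-aware)
    for (i in seq_len(nrow(annotation$utrs))) {
      u <- annotation$utrs[i, ]
      s <- useqs[[u$gene_id]]
      gseq <- annotation$genome[[u$chrom]]
      piece <- if (u$strand == "-") revcomp_dna(s) else s
      substr(gseq, u$start + 1L, u$end) <- piece
      annotation$genome[[u$chrom]] <- gseq
    }
    peaks <- bind_rows(peaks) |> arrange(.data$chrom, .data$start)
    long <- peaks$end - peaks$start > utr_len
    if (any(long)) abort("peak longer than the 3'UTR")
    truth$planted_sites <- bind_rows(planted)
    list(peaks = peaks, annotation = annotation, truth = truth)
  })
}

# Mutate bases until no pattern overlaps [s, e) of seq (0-based half-open).
# Used to guarantee decoy footprints carry no qualifying seed site.
scrub_patterns <- function(seq, patterns, s, e) {
  for (iter in 1:50) {
    hit <- FALSE
    for (pat in patterns) {
      idx <- fixed_matches(seq, pat)
      idx <- idx[idx + nchar(pat) > s & idx < e]   # any overlap with footprint
      for (p0 in idx) {
        hit <- TRUE
        mid <- p0 + nchar(pat) %/% 2L
        cur <- substr(seq, mid + 1L, mid + 1L)
        repl <- setdiff(c("A", "C", "G", "T"), cur)[1]
        substr(seq, mid + 1L, mid + 1L) <- repl
      }
    }
    if (!hit) return(seq)
  }
  abort("failed to scrub decoy footprint of seed sites")
}
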