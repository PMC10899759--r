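#' Sequence alphabet helpers
#'
#' Internally targets are handled in the DNA alphabet (U converted to T) and
#' miRNAs in RNA; both are upper-cased at the boundary.
#' @param x character vector of sequences.
#' @return normalized character vector.
#' @keywords internal
#' @name alphabet
NULL

#' @rdname alphabet
norm_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @rdname alphabet
norm_rna <- function(x) chartr("t", "U", chartr("T", "U", toupper(x)))

revcomp_dna <- function(x) {
  vapply(strsplit(chartr("ACGTacgtN", "TGCATGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Extract a miRNA seed (nucleotides 2-8)
#'
#' The seed is the 7-mer at 1-based positions 2-8 of the mature miRNA;
#' miRNAs sharing it form a seed family with a shared target repertoire.
#'
#' @param sequence mature miRNA sequence(s), 5' to 3'; T/U and case are
#'   normalized.
#' @return character vector of 7-mer seeds in the RNA alphabet.
#' @examples
#' seed_of("UGAGGUAGUAGGUUGU")  # "GAGGUAG"
#' @export
seed_of <- function(sequence) {
  sequence <- norm_rna(sequence)
  if (any(nchar(sequence) < 8)) {
    abort("miRNA sequences must be at least 8 nt to define a nt 2-8 seed")
  }
  substr(sequence, 2L, 8L)
}

# Target-strand patterns (DNA, 5'->3') matched by each canonical site type.
# The site pairs antiparallel with miRNA nt 2-8 (m8 type) or 2-7 plus a
# literal target adenosine opposite miRNA position 1 (A1 types).
site_patterns <- function(seed_rna) {
  seed_dna <- norm_dna(seed_rna)
  rc28 <- revcomp_dna(seed_dna)                    # complements m8..m2
  rc27 <- revcomp_dna(substr(seed_dna, 1L, 6L))    # complements m7..m2
  list(`8mer` = paste0(rc28, "A"), `7mer-m8` = rc28, `7mer-A1` = paste0(rc27, "A"))
}

fixed_matches <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L  # 0-based
}

#' Scan a 3'UTR for canonical miRNA seed-match sites
#'
#' Reports every 8mer, 7mer-m8 and 7mer-A1 site for the miRNA's nt 2-8 seed
#' in a target sequence. Site types follow the canonical strong-site
#' convention: 7mer-m8 is the perfect antiparallel Watson-Crick match to
#' miRNA nt 2-8; the A1 types additionally require a literal adenosine in the
#' target opposite miRNA position 1 (not complementarity to nt 1); 8mer is
#' both. Overlapping matches at one locus are reported once with the
#' strongest type (8mer > 7mer-m8 > 7mer-A1); G:U wobbles and ambiguous
#' bases never match.
#'
#' @param utr_sequence target sequence (DNA or RNA; normalized to DNA),
#'   5' to 3'.
#' @param mirna_sequence mature miRNA sequence (>= 8 nt).
#' @return tibble with columns `start`, `end` (0-based half-open offsets in
#'   the target), `site_type` and `family_seed`, ordered by `start`.
#' @export
site_match <- function(utr_sequence, mirna_sequence) {
  stopifnot(length(utr_sequence) == 1L, length(mirna_sequence) == 1L)
  utr <- norm_dna(utr_sequence)
  seed <- seed_of(mirna_sequence)
  pat <- site_patterns(seed)
  # 8mer and 7mer-m8 share the nt 2-8 core: a core match followed by A is 8mer.
  core <- fixed_matches(utr, pat[["7mer-m8"]])
  followed_by_a <- if (length(core)) {
    substring(utr, core + 8L, core + 8L) == "A"
  } else {
    logical(0)
  }
  eight <- core[followed_by_a]
  m8 <- core[!followed_by_a]
  # A 7mer-A1 whose hexamer core extends a nt 2-8 match is subsumed by the
  # 8mer at the preceding offset; drop it.
  a1 <- fixed_matches(utr, pat[["7mer-A1"]])
  a1 <- a1[!(a1 - 1L) %in% eight]
  starts <- c(eight, m8, a1)
  ends <- c(eight + 8L, m8 + 7L, a1 + 7L)
  types <- rep(c("8mer", "7mer-m8", "7mer-A1"),
               c(length(eight), length(m8), length(a1)))
  # strongest type wins at a shared offset (8mer > 7mer-m8 > 7mer-A1)
  o <- order(starts, match(types, c("8mer", "7mer-m8", "7mer-A1")))
  o <- o[!duplicated(starts[o])]
  tibble(start = starts[o], end = ends[o], site_type = types[o],
         family_seed = rep_len(seed, length(o)))
}

#' Group miRNAs into seed families and rank them by abundance
#'
#' Partitions miRNAs by their nt 2-8 seed, sums member expression (TMM-CPM)
#' per sample, and ranks families by mean CPM over the ranking samples. The
#' default ranking condition is the high-density samples when a design is
#' supplied (abundance "at high cell density"); otherwise all samples are
#' pooled.
#'
#' @param mirnas tibble with columns `name` and `sequence`.
#' @param smallrna_counts small-RNA count tibble (first column miRNA id,
#'   remaining columns samples).
#' @param design optional tibble (sample, condition).
#' @param rank_condition condition whose samples drive the ranking; `NULL`
#'   pools all samples.
#' @param top_k number of families to flag as `top_family`.
#' @return tibble of families (one row per seed) with columns `family_seed`,
#'   `members`, `n_members`, `mean_cpm`, `rank`, `top_family`, plus a
#'   `cpm` list-column of per-sample summed family CPM. Ties in mean CPM
#'   break lexicographically by seed.
#' @export
group_families <- function(mirnas, smallrna_counts, design = NULL,
                           rank_condition = if (!is.null(design)) "high" else NULL,
                           top_k = 20) {
  stopifnot(all(c("name", "sequence") %in% names(mirnas)))
  m <- counts_to_matrix(smallrna_counts)
  unknown <- setdiff(rownames(m), mirnas$name)
  if (length(unknown)) {
    warn(paste0("miRNAs in counts but absent from sequences, excluded: ",
                paste(unknown, collapse = ", ")))
    m <- m[!rownames(m) %in% unknown, , drop = FALSE]
  }
  fac <- tmm_factors(matrix_to_counts(m, "mirna"))
  cpm_m <- counts_to_matrix(cpm(matrix_to_counts(m, "mirna"), fac))
  samples <- colnames(cpm_m)
  if (!is.null(rank_condition)) {
    if (is.null(design)) abort("`rank_condition` requires a design")
    check_design(design, samples)
    keep <- design$sample[design$condition == rank_condition]
    if (!length(keep)) abort(sprintf("no samples with condition '%s'", rank_condition))
    rank_samples <- intersect(samples, keep)
  } else {
    rank_samples <- samples
  }
  seeds <- setNames(seed_of(mirnas$sequence), mirnas$name)
  expressed <- intersect(mirnas$name, rownames(cpm_m))
  fam <- tibble(name = expressed, family_seed = unname(seeds[expressed])) |>
    group_by(.data$family_seed) |>
    summarise(members = list(.data$name), n_members = dplyr::n(), .groups = "drop")
  fam$cpm <- map(fam$members, function(mem) {
    colSums(cpm_m[mem, , drop = FALSE])
  })
  fam$mean_cpm <- map_dbl(fam$cpm, function(v) mean(v[rank_samples]))
  fam <- fam |>
    arrange(desc(.data$mean_cpm), .data$family_seed) |>
    mutate(rank = row_number(), top_family = .data$rank <= top_k)
  fam
}

#' Annotate eCLIP peaks with genomic region and seed sites
#'
#' Assigns each peak the feature class it maximally overlaps (3'UTR > exon >
#' intron, intergenic otherwise), maps 3'UTR peaks into strand-aware UTR
#' coordinates, and scans the peak footprint for seed sites of the supplied
#' (typically top-ranked) families. Sites are required to lie entirely within
#' the peak footprint.
#'
#' @param peaks tibble with columns chrom, start, end (0-based half-open),
#'   gene_id, strand, compartment.
#' @param annotation a `sim_annotation` or object read by
#'   [read_annotation_gff3()].
#' @param families output of [group_families()]; only rows with
#'   `top_family == TRUE` are scanned.
#' @param utr_seqs optional named character vector of UTR sequences
#'   (defaults to [utr_sequences()] of the annotation).
#' @return list with `peaks` (input plus `region` and `n_sites`) and `sites`
#'   (gene_id, peak_id, utr_start, utr_end, site_type, family_seed).
#' @export
annotate_peaks <- function(peaks, annotation, families,
                           utr_seqs = utr_sequences(annotation)) {
  stopifnot(all(c("chrom", "start", "end", "gene_id", "strand", "compartment")
                %in% names(peaks)))
  known <- peaks$chrom %in% names(annotation$genome)
  if (any(!known)) {
    inform(sprintf("skipping %d peak(s) on unannotated contigs", sum(!known)))
    peaks <- peaks[known, , drop = FALSE]
  }
  peaks <- peaks |> mutate(peak_id = sprintf("peak%05d", row_number()))
  ov <- function(feat, p) {
    f <- feat[feat$gene_id == p$gene_id, , drop = FALSE]
    if (!nrow(f)) return(0L)
    sum(pmax(0L, pmin(f$end, p$end) - pmax(f$start, p$start)))
  }
  seeds <- families$family_seed[families$top_family]
  pats <- map(seeds, site_patterns)
  site_rows <- list()
  region <- character(nrow(peaks))
  n_sites <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    ovs <- c(utr = ov(annotation$utrs, p), exon = ov(annotation$exons, p),
             intron = ov(annotation$introns, p))
    # UTR overlap counts once: exon overlap excludes the UTR portion
    ovs["exon"] <- max(0L, ovs["exon"] - ovs["utr"])
    region[i] <- if (all(ovs == 0)) "intergenic" else
      c("three_prime_utr", "exon", "intron")[which.max(ovs)]
    if (region[i] != "three_prime_utr") next
    u <- annotation$utrs[annotation$utrs$gene_id == p$gene_id, ]
    useq <- utr_seqs[[p$gene_id]]
    if (is.null(useq)) next
    # strand-aware genome -> UTR transcript frame (0-based half-open)
    if (u$strand == "+") {
      fs <- max(0L, p$start - u$start); fe <- min(nchar(useq), p$end - u$start)
    } else {
      fs <- max(0L, u$end - p$end); fe <- min(nchar(useq), u$end - p$start)
    }
    if (fe <= fs) next
    hits <- bind_rows(imap(seeds, function(s, j) {
      site_match(useq, paste0("N", s))  # dummy nt1; seed drives matching
    }))
    if (nrow(hits)) {
      hits <- hits |> filter(.data$start >= fs, .data$end <= fe)
    }
    if (nrow(hits)) {
      site_rows[[length(site_rows) + 1L]] <- hits |>
        mutate(gene_id = p$gene_id, peak_id = p$peak_id) |>
        select("gene_id", "peak_id", utr_start = "start", utr_end = "end",
               "site_type", "family_seed")
      n_sites[i] <- nrow(hits)
    }
  }
  sites <- if (length(site_rows)) bind_rows(site_rows) else
    tibble(gene_id = character(), peak_id = character(),
           utr_start = integer(), utr_end = integer(),
           site_type = character(), family_seed = character())
  list(peaks = peaks |> mutate(region = region, n_sites = n_sites),
       sites = sites)
}

#' Tally qualifying cytoplasmic 3'UTR peaks per gene
#'
#' @param annotated output of [annotate_peaks()].
#' @param site_types site types that qualify a peak.
#' @param compartment compartment filter.
#' @return tibble (gene_id, n_utr_peaks, n_utr_sites, families) counting, per
#'   gene, cytoplasmic 3'UTR peaks holding at least one qualifying site.
#' @export
count_utr_sites <- function(annotated,
                            site_types = c("8mer", "7mer-m8", "7mer-A1"),
                            compartment = "cytoplasm") {
  pk <- annotated$peaks |>
    filter(.data$compartment == !!compartment, .data$region == "three_prime_utr")
  st <- annotated$sites |>
    filter(.data$site_type %in% site_types, .data$peak_id %in% pk$peak_id)
  if (!nrow(st)) {
    return(tibble(gene_id = character(), n_utr_peaks = integer(),
                  n_utr_sites = integer(), families = list()))
  }
  st |>
    group_by(.data$gene_id) |>
    summarise(n_utr_peaks = dplyr::n_distinct(.data$peak_id),
              n_utr_sites = dplyr::n(),
              families = list(sort(unique(.data$family_seed))),
              .groups = "drop")
}
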