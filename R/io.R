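#' Write a simulated dataset to standard file formats
#'
#' Emits GFF3 (1-based closed, features gene/exon/three_prime_UTR), FASTA
#' (genome, 3'UTRs, mature miRNAs), BED6+1 peaks (0-based half-open, name =
#' gene id, column 7 = compartment), TSV count matrices, the design, the Ct
#' table, the densitometry tables, and `truth.json`. Identical inputs yield
#' byte-identical files.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  ann <- sim$annotation

  feat <- bind_rows(
    ann$genes |> mutate(type = "gene", ID = .data$gene_id),
    ann$exons |> mutate(type = "exon",
                        ID = sprintf("%s.e%d", .data$gene_id, .data$exon_rank)),
    ann$utrs |> mutate(type = "three_prime_UTR",
                       ID = paste0(.data$gene_id, ".utr"))
  ) |> arrange(.data$start, match(.data$type, c("gene", "exon", "three_prime_UTR")))
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand, type = feat$type, ID = feat$ID, Parent = feat$gene_id)
  rtracklayer::export(gr, path("annotation.gff3"), format = "gff3")

  writeXStringSet <- Biostrings::writeXStringSet
  writeXStringSet(Biostrings::DNAStringSet(ann$genome), path("genome.fa"))
  writeXStringSet(Biostrings::DNAStringSet(utr_sequences(ann)), path("utr.fa"))
  writeXStringSet(Biostrings::RNAStringSet(
    setNames(sim$mirnome$mirnas$sequence, sim$mirnome$mirnas$name)),
    path("mirna.fa"))

  readr::write_tsv(
    sim$peaks |> select("chrom", "start", "end", name = "gene_id",
                        "score", "strand", "compartment"),
    path("peaks.bed"), col_names = FALSE)
  readr::write_tsv(sim$exonic, path("exonic.tsv"))
  readr::write_tsv(sim$intronic, path("intronic.tsv"))
  readr::write_tsv(sim$smallrna, path("smallrna.tsv"))
  readr::write_tsv(sim$design, path("design.tsv"))
  readr::write_tsv(sim$ct_table, path("ct.tsv"))
  readr::write_tsv(sim$densitometry$standards, path("densitometry_standards.tsv"))
  readr::write_tsv(sim$densitometry$samples, path("densitometry_fractions.tsv"))

  truth <- sim$truth
  jsonlite::write_json(
    list(candidates = truth$candidates,
         effects = truth$effects,
         planted_sites = truth$planted_sites,
         halflives = truth$halflives,
         copies_per_cell = truth$copies_per_cell,
         top_family_seeds = truth$top_family_seeds),
    path("truth.json"), digits = NA)

  invisible(list.files(outdir, full.names = TRUE))
}

#' Read a gene annotation from GFF3 (+ genome FASTA)
#'
#' Expects gene, exon and three_prime_UTR features keyed by a `Parent` (or
#' `ID`) gene attribute, as written by [write_simulation()]. Coordinates are
#' converted to the package's internal 0-based half-open frame and introns
#' are derived from exon gaps.
#'
#' @param gff3_path GFF3 file.
#' @param genome_fasta_path genome FASTA file.
#' @return a `sim_annotation`-shaped list (genes, exons, introns, utrs,
#'   genome).
#' @export
read_annotation_gff3 <- function(gff3_path, genome_fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df <- df |>
    mutate(
      chrom = as.character(.data$seqnames),
      start = .data$start - 1L,            # to 0-based half-open
      strand = as.character(.data$strand),
      gene_id = dplyr::coalesce(
        as.character(unlist(map(.data$Parent, function(p)
          if (length(p)) p[[1]] else NA_character_))),
        as.character(.data$ID))
    )
  genes <- df |> filter(.data$type == "gene") |>
    select("gene_id", "chrom", "start", "end", "strand")
  exons <- df |> filter(.data$type == "exon") |>
    group_by(.data$gene_id) |> arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = row_number()) |> ungroup() |>
    select("gene_id", "chrom", "exon_rank", "start", "end", "strand")
  utrs <- df |> filter(.data$type == "three_prime_UTR") |>
    select("gene_id", "chrom", "start", "end", "strand")
  introns <- exons |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    dplyr::reframe(chrom = .data$chrom[1], strand = .data$strand[1],
                   istart = head(.data$end, -1), iend = tail(.data$start, -1)) |>
    select("gene_id", "chrom", start = "istart", end = "iend", "strand")
  genome_set <- Biostrings::readDNAStringSet(genome_fasta_path)
  genome <- setNames(as.character(genome_set), names(genome_set))
  structure(list(genes = genes, exons = exons, introns = introns,
                 utrs = utrs, genome = genome),
            class = "sim_annotation")
}

#' Read an eCLIP peak BED6+1 file
#'
#' BED columns chrom, start, end, name (gene id), score, strand plus a
#' seventh `compartment` column (`cyto`/`nuc` or full words).
#'
#' @param bed_path BED file path.
#' @return tibble (chrom, start, end, gene_id, score, strand, compartment).
#' @export
read_peaks_bed <- function(bed_path) {
  gr <- rtracklayer::import(
    bed_path, format = "bed", extraCols = c(compartment = "character"))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = gr$name,
    score = as.integer(gr$score),
    strand = as.character(GenomicRanges::strand(gr)),
    compartment = dplyr::recode(gr$compartment,
                                cyto = "cytoplasm", nuc = "nucleus")
  )
}

#' Read sequences from FASTA as a named character vector
#'
#' @param fasta_path FASTA file.
#' @param alphabet "DNA" or "RNA".
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(fasta_path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "DNA") Biostrings::readDNAStringSet(fasta_path)
         else Biostrings::readRNAStringSet(fasta_path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Read a TSV count matrix
#'
#' @param tsv_path TSV with a leading id column and one column per sample.
#' @return count tibble.
#' @export
read_counts_tsv <- function(tsv_path) {
  readr::read_tsv(tsv_path, show_col_types = FALSE)
}
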