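#' Simulate a gene annotation and genome sequence
#'
#' Generates a single-chromosome genome of non-overlapping multi-exon genes,
#' each with at least two exons (so every gene has intronic signal for
#' exon-intron split analysis) and a 3'UTR of fixed length occupying the
#' 3' end of the terminal exon. Genes are laid left to right with random
#' intergenic gaps and random strands; gene bodies never overlap, a
#' prerequisite for attributing intronic reads unambiguously.
#'
#' Coordinates are 0-based half-open internally ([write_simulation()] converts
#' to 1-based closed GFF3 on export).
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_annotation`: list with tibbles `genes`
#'   (gene_id, chrom, start, end, strand), `exons`, `introns`, `utrs`, and
#'   `genome`, a named character vector of chromosome sequences.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0L) abort("cannot simulate an empty annotation (n_genes = 0)")
  withr::with_seed(sub_seed(cfg$rng_seed, 1L), {
    chrom <- "simchr1"
    utr_len <- cfg$utr_length_nt
    genes <- vector("list", cfg$n_genes)
    exons <- vector("list", cfg$n_genes)
    cursor <- sample(200:800, 1)
    for (i in seq_len(cfg$n_genes)) {
      gid <- sprintf("G%04d", i)
      strand <- sample(c("+", "-"), 1)
      n_exons <- sample(2:5, 1)
      exon_len <- sample(150:400, n_exons, replace = TRUE)
      # terminal exon (transcript order) must hold the full UTR plus coding room
      term <- if (strand == "+") n_exons else 1L
      exon_len[term] <- utr_len + sample(100:250, 1)
      intron_len <- sample(200:800, n_exons - 1, replace = TRUE)
      starts <- cursor + cumsum(c(0, head(exon_len, -1) + intron_len))
      ends <- starts + exon_len
      exons[[i]] <- tibble(
        gene_id = gid, chrom = chrom, exon_rank = seq_len(n_exons),
        start = starts, end = ends, strand = strand
      )
      genes[[i]] <- tibble(
        gene_id = gid, chrom = chrom, start = starts[1],
        end = ends[n_exons], strand = strand
      )
      cursor <- ends[n_exons] + sample(500:1500, 1)
    }
    genes <- bind_rows(genes)
    exons <- bind_rows(exons)
    utrs <- exons |>
      group_by(.data$gene_id) |>
      summarise(
        chrom = .data$chrom[1], strand = .data$strand[1],
        lo = min(.data$start), hi = max(.data$end), .groups = "drop"
      ) |>
      mutate(
        start = if_else(.data$strand == "+", .data$hi - utr_len, .data$lo),
        end = if_else(.data$strand == "+", .data$hi, .data$lo + utr_len)
      ) |>
      select("gene_id", "chrom", "start", "end", "strand")
    introns <- exons |>
      arrange(.data$gene_id, .data$start) |>
      group_by(.data$gene_id) |>
      dplyr::reframe(
        chrom = .data$chrom[1], strand = .data$strand[1],
        istart = head(.data$end, -1), iend = tail(.data$start, -1)
      ) |>
      select("gene_id", "chrom", start = "istart", end = "iend", "strand")
    genome_len <- max(genes$end) + 500
    genome_seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                        collapse = "")
    structure(
      list(genes = genes, exons = exons, introns = introns, utrs = utrs,
           genome = setNames(genome_seq, chrom)),
      class = "sim_annotation"
    )
  })
}

#' Extract strand-aware 3'UTR sequences
#'
#' @param annotation a `sim_annotation` (or any list with `utrs` and `genome`
#'   in the same shape).
#' @return named character vector of UTR sequences, 5' to 3' in transcript
#'   orientation, keyed by gene id.
#' @export
utr_sequences <- function(annotation) {
  utrs <- annotation$utrs
  out <- map_chr(seq_len(nrow(utrs)), function(i) {
    s <- substr(annotation$genome[[utrs$chrom[i]]], utrs$start[i] + 1, utrs$end[i])
    if (utrs$strand[i] == "-") revcomp_dna(s) else s
  })
  setNames(out, utrs$gene_id)
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat(sprintf("<sim_annotation> %d genes on %s (%d nt)\n",
              nrow(x$genes), names(x$genome)[1], nchar(x$genome[[1]])))
  invisible(x)
}
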