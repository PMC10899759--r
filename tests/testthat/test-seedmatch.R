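test_that("seed_of extracts nucleotides 2-8 and normalizes the alphabet", {
  expect_equal(seed_of("UGAGGUAGUAGGUUGU"), "GAGGUAG")
  expect_equal(seed_of("tgaggtagtaggttgt"), "GAGGUAG")
  # seeds depend only on the first 8 nt: 3' extensions are irrelevant
  expect_equal(seed_of("UGAGGUAG"), seed_of("UGAGGUAGCCCCCCCCCCCC"))
  expect_error(seed_of("UGAGGUA"), "at least 8")
  set.seed(5)
  for (i in 1:20) {
    s <- random_rna(22)
    expect_equal(seed_of(s), paste(strsplit(s, "")[[1]][2:8], collapse = ""))
  }
})

test_that("site_match finds the three canonical site types for a known seed", {
  mir <- "UGAGGUAGUAGGUUGU"  # seed GAGGUAG
  hit8 <- site_match("GGGGCTACCTCAGGG", mir)
  expect_equal(hit8$site_type, "8mer")
  expect_equal(hit8$end - hit8$start, 8L)
  hitm8 <- site_match("GGGGCTACCTCGGGG", mir)   # core without trailing A
  expect_equal(hitm8$site_type, "7mer-m8")
  hita1 <- site_match("GGGGTACCTCAGGGG", mir)   # hexamer core plus A
  expect_equal(hita1$site_type, "7mer-A1")
  # base-by-base antiparallel re-check of each reported site
  for (h in list(hit8, hitm8, hita1)) {
    o <- brute_site_scan(if (h$site_type == "8mer") "GGGGCTACCTCAGGG"
                         else if (h$site_type == "7mer-m8") "GGGGCTACCTCGGGG"
                         else "GGGGTACCTCAGGGG", mir)
    expect_equal(h$start, o$start)
    expect_equal(h$site_type, o$site_type)
  }
  expect_equal(nrow(site_match("GGGGGGG", mir)), 0L)
})

test_that("site_match equals the exhaustive per-offset pairing oracle", {
  set.seed(101)
  for (i in 1:150) {
    utr <- random_dna(sample(30:120, 1))
    mir <- random_rna(sample(20:24, 1))
    got <- site_match(utr, mir)
    want <- brute_site_scan(utr, mir)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("site_match is invariant under case and U/T target alphabet", {
  set.seed(7)
  utr <- random_dna(80)
  mir <- random_rna(22)
  base <- site_match(utr, mir)
  expect_equal(site_match(tolower(utr), mir), base)
  expect_equal(site_match(chartr("T", "U", utr), mir), base)
})

test_that("no offset carries two site types and N never matches", {
  set.seed(13)
  for (i in 1:30) {
    got <- site_match(random_dna(100), random_rna(22))
    expect_equal(anyDuplicated(got$start), 0L)
  }
  expect_equal(nrow(site_match("CTNCCTCA", "UGAGGUAGUAGGUUGU")), 0L)
})

test_that("group_families partitions by seed, sums CPM and ranks", {
  mirnas <- tibble::tibble(
    name = c("mA", "mB", "mC"),
    sequence = c("UGAGGUAGAAAAAAAAAAAA", "CGAGGUAGCCCCCCCCCCCC",
                 "UAAAAAAACCCCCCCCCCCC"))
  cnts <- counts_tbl(matrix(c(100, 100, 50, 50, 400, 400), nrow = 3,
                            byrow = TRUE,
                            dimnames = list(c("mA", "mB", "mC"),
                                            c("s1", "s2"))), id = "mirna")
  fam <- group_families(mirnas, cnts, top_k = 1)
  expect_equal(nrow(fam), 2L)
  shared <- fam[fam$family_seed == "GAGGUAG", ]
  expect_equal(shared$n_members, 2L)
  # additivity: family CPM is the member sum
  total <- colSums(miriscshift:::counts_to_matrix(cnts))
  expect_equal(unname(shared$cpm[[1]]["s1"]),
               unname((100 + 50) / total["s1"] * 1e6 /
                        tmm_factors(cnts)$norm_factor[1]))
  expect_equal(fam$rank[fam$family_seed == "AAAAAAA"], 1L)
  expect_true(fam$top_family[fam$rank == 1])
})

test_that("group_families warns on and excludes miRNAs missing a sequence", {
  mirnas <- tibble::tibble(
    name = c("mA", "mB"),
    sequence = c("UGAGGUAGAAAAAAAAAAAA", "UAAAAAAACCCCCCCCCCCC"))
  cnts <- counts_tbl(matrix(c(10, 10, 30, 30, 20, 20), nrow = 3, byrow = TRUE,
                            dimnames = list(c("mA", "mB", "ghost"),
                                            c("s1", "s2"))),
                     id = "mirna")
  expect_warning(fam <- group_families(mirnas, cnts, top_k = 5), "ghost")
  expect_equal(nrow(fam), 2L)
})

test_that("distinct seeds give one family per miRNA; shared seeds merge", {
  cfg <- small_cfg(rng_seed = 31)
  mn <- simulate_mirnome(cfg)
  recomputed <- seed_of(mn$mirnas$sequence)
  expect_equal(recomputed, mn$mirnas$seed)
  expect_equal(length(unique(recomputed)), cfg$n_families)
})

test_that("annotate_peaks assigns regions and respects strand", {
  cfg <- small_cfg(rng_seed = 17)
  sim <- simulate_dataset(cfg)
  fam <- group_families(sim$mirnome$mirnas, sim$smallrna, design = sim$design,
                        top_k = cfg$top_k_families)
  ann <- annotate_peaks(sim$peaks, sim$annotation, fam)
  intronic <- ann$peaks$region[ann$peaks$start %in%
    (sim$annotation$introns$start + 1L)]
  expect_true(all(intronic == "intron"))
  # every reported site has a canonical footprint length
  expect_true(all(ann$sites$utr_end - ann$sites$utr_start %in% c(7L, 8L)))
})

test_that("minus-strand genes yield the same sites as the reverse-complement UTR", {
  cfg <- small_cfg(rng_seed = 23)
  sim <- simulate_dataset(cfg)
  useqs <- utr_sequences(sim$annotation)
  minus <- sim$annotation$utrs |> dplyr::filter(strand == "-")
  expect_gt(nrow(minus), 0)
  g <- minus$gene_id[1]
  mir <- sim$mirnome$mirnas$sequence[1]
  # scanning the transcript-frame UTR directly equals scanning the
  # reverse-complement of the genomic plus-strand slice
  genomic <- substr(sim$annotation$genome[[minus$chrom[1]]],
                    minus$start[1] + 1, minus$end[1])
  expect_equal(site_match(useqs[[g]], mir),
               site_match(miriscshift:::revcomp_dna(genomic), mir))
})
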