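# Independent oracles, kept free of any code path they check.

# Watson-Crick pairing of a DNA target base with an RNA miRNA base
# (antiparallel; no wobble).
wc_pairs <- function(target_base, mirna_base) {
  paste0(target_base, mirna_base) %in% c("AU", "TA", "CG", "GC")
}

# Exhaustive per-offset seed-site scan by base-by-base antiparallel pairing.
# Target position i+j pairs miRNA position 8-j (m8 core) or 7-j (A1 hexamer
# core); the A1/8mer adenosine is a literal target A. Strongest type wins at
# an offset; an A1 whose core extends a nt 2-8 match at the previous offset
# is subsumed by that site.
brute_site_scan <- function(utr, mirna) {
  utr <- chartr("U", "T", toupper(utr))
  mir <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tgt <- strsplit(utr, "")[[1]]
  n <- length(tgt)
  pairs_core <- function(i, first_m, last_m) {
    # target [i, i+len) pairs miRNA last_m..first_m antiparallel
    len <- last_m - first_m + 1L
    if (i + len - 1L > n) return(FALSE)
    all(vapply(seq_len(len), function(j) {
      wc_pairs(tgt[i + j - 1L], mir[last_m - j + 1L])
    }, logical(1)))
  }
  out <- list()
  for (i in seq_len(n)) {
    if (pairs_core(i, 2L, 8L)) {
      if (i + 7L <= n && tgt[i + 7L] == "A") {
        out[[length(out) + 1L]] <- list(start = i - 1L, end = i + 7L, type = "8mer")
      } else {
        out[[length(out) + 1L]] <- list(start = i - 1L, end = i + 6L, type = "7mer-m8")
      }
    } else if (pairs_core(i, 2L, 7L) && i + 6L <= n && tgt[i + 6L] == "A" &&
               !(i >= 2L && pairs_core(i - 1L, 2L, 8L))) {
      out[[length(out) + 1L]] <- list(start = i - 1L, end = i + 6L, type = "7mer-A1")
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          site_type = character()))
  }
  tibble::tibble(
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    site_type = vapply(out, `[[`, character(1), "type")
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# Exhaustive conditional enumeration of the equal-library Poisson split test.
binom_split_pvalue <- function(s_a, t, n_a, n_b) {
  s <- 0:t
  pr <- exp(lchoose(t, s) + s * log(n_a / (n_a + n_b)) +
              (t - s) * log(n_b / (n_a + n_b)))
  pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[s <= s_a]), sum(pr[s >= s_a])))
}
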