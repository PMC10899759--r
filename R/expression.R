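#' Counts per million
#'
#' @param counts count tibble (first column feature id, then samples).
#' @param norm_factors optional [tmm_factors()] output; when supplied the
#'   effective library size (library size x TMM factor) is used.
#' @param log return log2(CPM + prior)?
#' @param prior pseudocount added before log2.
#' @return tibble of the same shape with CPM values.
#' @export
cpm <- function(counts, norm_factors = NULL, log = FALSE, prior = 0.5) {
  m <- counts_to_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) abort("all-zero sample column: CPM undefined")
  if (!is.null(norm_factors)) {
    stopifnot(all(colnames(m) %in% norm_factors$sample))
    eff <- norm_factors$eff_lib_size[match(colnames(m), norm_factors$sample)]
  } else {
    eff <- lib
  }
  out <- sweep(m, 2, eff, "/") * 1e6
  if (log) out <- log2(out + prior)
  res <- matrix_to_counts(out, names(counts)[1])
  names(res) <- names(counts)
  res
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors: for each sample against
#' the reference (the sample whose 75th-percentile CPM is closest to the mean
#' of those percentiles), gene-wise log ratios M and average log abundances A
#' are formed from library-size-scaled counts, genes with zero counts in
#' either sample are excluded, the top and bottom `trim_m` of M and `trim_a`
#' of A are trimmed, and the factor is 2 to the weighted mean of the
#' remaining M values with inverse approximate binomial variance weights.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts count tibble (first column feature id, then samples).
#' @param trim_m two-sided trim fraction on M values.
#' @param trim_a two-sided trim fraction on A values.
#' @param do_weighting use inverse-variance weights (delta-method binomial
#'   approximation)?
#' @return tibble (sample, lib_size, norm_factor, eff_lib_size) of class
#'   `norm_factors`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        do_weighting = TRUE) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2L) abort("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) abort("all-zero sample column")
  f75 <- map_dbl(seq_len(ncol(m)), function(j) {
    quantile(m[, j], 0.75, names = FALSE) / lib[j]
  })
  ref <- which.min(abs(f75 - mean(f75)))
  f <- map_dbl(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref], lib[j], lib[ref], trim_m, trim_a, do_weighting)
  })
  f <- f / geo_mean(f)
  structure(
    tibble(sample = colnames(m), lib_size = unname(lib), norm_factor = f,
           eff_lib_size = unname(lib) * f),
    class = c("norm_factors", class(tibble())))
}

# One observation/reference TMM factor (doubly trimmed weighted mean of M).
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, do_weighting) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) < 2L) {
    warn("fewer than 2 genes shared and nonzero; TMM factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

# Moderated method-of-moments NB dispersion on library-equalized counts:
# per-gene raw estimates are shrunk halfway toward the common (mean) value.
estimate_dispersion <- function(pseudo, groups, shrink = 0.5) {
  per_group <- map(unique(groups), function(g) {
    x <- pseudo[, groups == g, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    (v - mu) / mu^2
  })
  raw <- Reduce(`+`, per_group) / length(per_group)
  raw[!is.finite(raw)] <- 0
  common <- max(0, mean(raw))
  # truncate at zero before shrinking: dispersions are non-negative, and
  # clamping after shrinkage would systematically deflate low-raw genes
  phi <- shrink * pmax(0, raw) + (1 - shrink) * common
  list(phi = phi, common = common)
}

# Exact conditional two-sided p-value for the split of total t between nA and
# nB samples under a common-mean NB (Poisson when phi = 0). The conditional
# law of the group-A sum given the total is free of the mean: negative
# hypergeometric with shape nA/phi, nB/phi (binomial in the Poisson limit).
# Two-sided by doubling the smaller tail, capped at 1.
exact_nb_pvalue <- function(s_a, t, n_a, n_b, phi) {
  if (t == 0) return(1)
  s <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(s, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    rA <- n_a / phi; rB <- n_b / phi
    logp <- lgamma(s + rA) - lgamma(s + 1) +
      lgamma(t - s + rB) - lgamma(t - s + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pl <- sum(p[s <= s_a]); pr <- sum(p[s >= s_a])
  min(1, 2 * min(pl, pr))
}

#' Negative-binomial exact test for differential expression
#'
#' Two-group exact test in the style of the classic NB exact test: effective
#' library sizes (TMM) are equalized by proportional scaling to their
#' geometric mean, per-gene dispersions are moderated method-of-moments
#' estimates shrunk 50% toward the common dispersion, and the p-value comes
#' from the exact conditional distribution of the group-B sum given the
#' total, two-sided by doubling the smaller tail. Log2 fold changes
#' (`condition_b` vs `condition_a`) use CPM means with a pseudocount.
#'
#' @param counts count tibble (first column gene id, then samples).
#' @param design tibble (sample, condition).
#' @param condition_a,condition_b the two condition labels; fold changes are
#'   `condition_b` relative to `condition_a`.
#' @param norm_factors optional precomputed [tmm_factors()].
#' @param dispersion optional fixed NB dispersion (scalar or per-gene vector);
#'   overrides the moderated method-of-moments estimate. 0 gives the exact
#'   Poisson (binomial conditional) test.
#' @param pseudocount CPM pseudocount for log2 fold changes.
#' @return tibble of class `de_result`: gene, log2fc, pvalue, fdr, mean_cpm.
#' @export
nb_exact_test <- function(counts, design, condition_a = "low",
                          condition_b = "high", norm_factors = NULL,
                          dispersion = NULL, pseudocount = 0.5) {
  m <- counts_to_matrix(counts)
  check_design(design, colnames(m))
  cond <- design$condition[match(colnames(m), design$sample)]
  a_cols <- which(cond == condition_a); b_cols <- which(cond == condition_b)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    abort("need at least 2 replicates per condition")
  }
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- norm_factors$eff_lib_size[match(colnames(m), norm_factors$sample)]
  n_star <- geo_mean(eff)
  pseudo <- sweep(m, 2, n_star / eff, "*")
  disp <- if (is.null(dispersion)) {
    estimate_dispersion(pseudo[, c(a_cols, b_cols), drop = FALSE],
                        rep(c("a", "b"), c(length(a_cols), length(b_cols))))
  } else {
    list(phi = rep_len(dispersion, nrow(m)), common = mean(dispersion))
  }
  cpm_m <- counts_to_matrix(cpm(counts, norm_factors))
  mean_a <- rowMeans(cpm_m[, a_cols, drop = FALSE])
  mean_b <- rowMeans(cpm_m[, b_cols, drop = FALSE])
  log2fc <- log2(mean_b + pseudocount) - log2(mean_a + pseudocount)
  s_a <- round(rowSums(pseudo[, a_cols, drop = FALSE]))
  s_b <- round(rowSums(pseudo[, b_cols, drop = FALSE]))
  pv <- map_dbl(seq_len(nrow(m)), function(g) {
    tot <- s_a[g] + s_b[g]
    if (tot == 0) return(1)
    exact_nb_pvalue(s_a[g], tot, length(a_cols), length(b_cols), disp$phi[g])
  })
  zero <- (s_a + s_b) == 0
  log2fc[zero] <- 0
  out <- tibble(
    gene = rownames(m), log2fc = unname(log2fc), pvalue = pv,
    fdr = p.adjust(pv, method = "BH"),
    mean_cpm = unname(rowMeans(cpm_m))
  )
  class(out) <- c("de_result", class(out))
  attr(out, "conditions") <- c(condition_a, condition_b)
  attr(out, "common_dispersion") <- disp$common
  out
}
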