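#' Exon-intron split analysis
#'
#' Separates transcriptional from post-transcriptional regulation between two
#' conditions by contrasting exonic (mature mRNA) against intronic (pre-mRNA)
#' count changes. Exonic and intronic matrices are TMM-normalized
#' independently; genes are kept when their mean log2 normalized count
#' reaches `min_log2_mean` in both count types; `d_exon` and `d_intron` are
#' log2 fold changes of condition means (with pseudocount) and
#' `d_diff = d_exon - d_intron` isolates the post-transcriptional component.
#' Significance of `d_diff` comes from a per-gene NB log-linear model
#' `count ~ condition + count_type + condition:count_type` with effective
#' library-size offsets and a dispersion shared across genes, via a
#' likelihood-ratio test on the interaction.
#'
#' @param exonic,intronic count tibbles over the same gene universe (first
#'   column gene id, then samples).
#' @param design tibble (sample, condition).
#' @param condition_a,condition_b baseline and contrast condition labels.
#' @param min_log2_mean abundance filter on mean log2 normalized count
#'   (default 5, i.e. ~32 normalized reads).
#' @param pseudocount pseudocount for the log2 condition means.
#' @return tibble of class `eisa_result`: gene, d_exon, d_intron, d_diff,
#'   pvalue, fdr, plus fdr_intron (condition-only test on intronic counts,
#'   used by [classify_regulation()]).
#' @export
eisa <- function(exonic, intronic, design, condition_a = "low",
                 condition_b = "high", min_log2_mean = 5, pseudocount = 0.5) {
  me <- counts_to_matrix(exonic); mi <- counts_to_matrix(intronic)
  if (!identical(colnames(me), colnames(mi))) {
    abort("exonic and intronic matrices must share sample columns")
  }
  dropped <- union(setdiff(rownames(me), rownames(mi)),
                   setdiff(rownames(mi), rownames(me)))
  if (length(dropped)) {
    inform(sprintf("excluding %d gene(s) missing from one matrix", length(dropped)))
  }
  shared <- intersect(rownames(me), rownames(mi))
  me <- me[shared, , drop = FALSE]; mi <- mi[shared, , drop = FALSE]
  check_design(design, colnames(me))
  cond <- design$condition[match(colnames(me), design$sample)]
  if (sum(cond == condition_a) < 2L || sum(cond == condition_b) < 2L) {
    abort("need at least 2 replicates per condition")
  }
  fe <- tmm_factors(matrix_to_counts(me)); fi <- tmm_factors(matrix_to_counts(mi))
  ne <- sweep(me, 2, mean(fe$eff_lib_size) / fe$eff_lib_size, "*")
  ni <- sweep(mi, 2, mean(fi$eff_lib_size) / fi$eff_lib_size, "*")
  keep <- rowMeans(log2(ne + pseudocount)) >= min_log2_mean &
    rowMeans(log2(ni + pseudocount)) >= min_log2_mean
  me <- me[keep, , drop = FALSE]; mi <- mi[keep, , drop = FALSE]
  ne <- ne[keep, , drop = FALSE]; ni <- ni[keep, , drop = FALSE]
  if (!nrow(me)) abort("no genes pass the abundance filter")
  a <- cond == condition_a; b <- cond == condition_b
  d_exon <- log2(rowMeans(ne[, b, drop = FALSE]) + pseudocount) -
    log2(rowMeans(ne[, a, drop = FALSE]) + pseudocount)
  d_intron <- log2(rowMeans(ni[, b, drop = FALSE]) + pseudocount) -
    log2(rowMeans(ni[, a, drop = FALSE]) + pseudocount)

  # interaction LRT with shared dispersion
  use <- a | b
  y <- cbind(me[, use, drop = FALSE], mi[, use, drop = FALSE])
  off <- log(c(fe$eff_lib_size[match(colnames(me)[use], fe$sample)],
               fi$eff_lib_size[match(colnames(mi)[use], fi$sample)]))
  cond2 <- factor(rep(cond[use], 2), levels = c(condition_a, condition_b))
  type2 <- factor(rep(c("exon", "intron"), each = sum(use)),
                  levels = c("intron", "exon"))
  disp <- estimate_dispersion(
    cbind(sweep(ne[, use, drop = FALSE], 2, 0, "+"),
          ni[, use, drop = FALSE]),
    paste(as.character(cond2), as.character(type2)))
  phi <- disp$common
  fam <- if (phi > 1e-8) MASS::negative.binomial(theta = 1 / phi) else
    stats::poisson(link = "log")
  X1 <- stats::model.matrix(~ cond2 * type2)
  X0 <- stats::model.matrix(~ cond2 + type2)
  pv <- map_dbl(seq_len(nrow(y)), function(g) {
    yy <- y[g, ]
    f1 <- suppressWarnings(stats::glm.fit(X1, yy, family = fam, offset = off))
    f0 <- suppressWarnings(stats::glm.fit(X0, yy, family = fam, offset = off))
    stats::pchisq(max(0, f0$deviance - f1$deviance), df = 1, lower.tail = FALSE)
  })
  de_intron <- nb_exact_test(matrix_to_counts(mi), design, condition_a,
                             condition_b, norm_factors = fi,
                             pseudocount = pseudocount)
  out <- tibble(
    gene = rownames(me),
    d_exon = unname(d_exon), d_intron = unname(d_intron),
    d_diff = unname(d_exon - d_intron),
    pvalue = pv, fdr = p.adjust(pv, method = "BH"),
    fdr_intron = de_intron$fdr[match(rownames(me), de_intron$gene)]
  )
  class(out) <- c("eisa_result", class(out))
  attr(out, "conditions") <- c(condition_a, condition_b)
  attr(out, "common_dispersion") <- phi
  out
}

#' Classify genes as transcriptionally or post-transcriptionally regulated
#'
#' Fits the ordinary least-squares line of `d_exon` on `d_intron` over all
#' tested genes and classes each gene: `post_transcriptional` when the
#' interaction FDR is below `fdr_threshold`, `d_diff > 0` and the gene sits
#' above the best-fit line (positive residual); `transcriptional` when the
#' intron change dominates (`|d_intron| > |d_diff|`) and is itself
#' significant at the same FDR; `mixed` when the interaction is significant
#' but directionality is ambiguous; otherwise `unclassified`.
#'
#' @param result an `eisa_result`.
#' @param fdr_threshold FDR cutoff (default 0.001).
#' @return the input with `residual` and `class` columns added; the fitted
#'   line is in `attr(, "fit_line")` (intercept, slope).
#' @export
classify_regulation <- function(result, fdr_threshold = 0.001) {
  stopifnot(inherits(result, "eisa_result"))
  if (nrow(result) < 10L) abort("need >= 10 genes to fit the best-fit line")
  if (stats::sd(result$d_intron) < 1e-12) {
    abort("degenerate d_intron variance: best-fit line undefined")
  }
  fit <- lm(d_exon ~ d_intron, data = result)
  res <- result$d_exon - unname(stats::predict(fit, result))
  sig <- result$fdr < fdr_threshold
  cls <- dplyr::case_when(
    sig & result$d_diff > 0 & res > 0 ~ "post_transcriptional",
    abs(result$d_intron) > abs(result$d_diff) &
      result$fdr_intron < fdr_threshold ~ "transcriptional",
    sig ~ "mixed",
    TRUE ~ "unclassified"
  )
  out <- result |> mutate(residual = res, class = cls)
  class(out) <- class(result)
  attr(out, "conditions") <- attr(result, "conditions")
  attr(out, "fit_line") <- setNames(coef(fit), c("intercept", "slope"))
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}
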