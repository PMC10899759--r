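#' Relative abundance by the 2^-ddCt method
#'
#' Normalizes each target-gene Ct against the arithmetic mean Ct of the
#' reference genes measured in the same fraction, condition, timepoint and
#' replicate (equivalent to a geometric mean on the linear scale), anchors at
#' the mean delta-Ct of the first timepoint, and converts to relative
#' abundance `2^-ddCt`. Amplification efficiency is taken as exactly 2 per
#' cycle.
#'
#' @param ct_table tibble with columns gene, fraction, condition,
#'   timepoint_h, replicate, ct.
#' @param reference_genes character vector of reference gene names; rows with
#'   no matching reference measurement are dropped with a message.
#' @return the target-gene rows with `delta_ct`, `ddct` and `rel_abundance`
#'   columns added.
#' @export
relative_abundance <- function(ct_table,
                               reference_genes = c("HPRT1", "SNRNP200", "ZMYM4")) {
  needed <- c("gene", "fraction", "condition", "timepoint_h", "replicate", "ct")
  stopifnot(all(needed %in% names(ct_table)))
  refs <- ct_table |>
    filter(.data$gene %in% reference_genes) |>
    group_by(.data$fraction, .data$condition, .data$timepoint_h, .data$replicate) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  tg <- ct_table |> filter(!.data$gene %in% reference_genes)
  joined <- tg |>
    left_join(refs, by = c("fraction", "condition", "timepoint_h", "replicate"))
  n_drop <- sum(is.na(joined$ref_ct))
  if (n_drop) {
    inform(sprintf("dropping %d row(s) lacking reference measurements", n_drop))
    joined <- joined |> filter(!is.na(.data$ref_ct))
  }
  t0 <- min(joined$timepoint_h)
  joined |>
    mutate(delta_ct = .data$ct - .data$ref_ct) |>
    group_by(.data$gene, .data$fraction, .data$condition) |>
    mutate(ddct = .data$delta_ct -
             mean(.data$delta_ct[.data$timepoint_h == t0])) |>
    ungroup() |>
    mutate(rel_abundance = 2^(-.data$ddct))
}

#' Fit an exponential decay half-life
#'
#' Least-squares fit of `ln(abundance)` against time; the decay rate is the
#' negated slope and `t_half = ln(2) / k`. Points below `floor_frac` of the
#' initial abundance are excluded as plateau (late actinomycin-D timepoints
#' sit at the qPCR noise floor). Non-positive rates yield an infinite
#' half-life flag; fewer than `min_points` usable points yield an
#' `unestimable` flag (transcripts whose half-life is too long or too short
#' for the sampling grid).
#'
#' @param timepoints_h numeric vector of times (hours).
#' @param abundances relative abundances (same length).
#' @param min_points minimum usable points (default 4).
#' @param floor_frac plateau floor as a fraction of the fitted t = 0
#'   abundance (default 0.01).
#' @return object of class `halflife_fit`: list with `k` (per hour),
#'   `t_half_h`, `se_k`, `r_squared`, `n_points`, `flag` (`ok`, `stable`,
#'   `unestimable`).
#' @export
fit_halflife <- function(timepoints_h, abundances, min_points = 4,
                         floor_frac = 0.01) {
  stopifnot(length(timepoints_h) == length(abundances))
  ok <- is.finite(timepoints_h) & is.finite(abundances) & abundances > 0
  t <- timepoints_h[ok]; a <- abundances[ok]
  a0 <- mean(a[t == min(t)])
  use <- a > floor_frac * a0
  t <- t[use]; a <- a[use]
  out <- list(k = NA_real_, t_half_h = NA_real_, se_k = NA_real_,
              r_squared = NA_real_, n_points = length(t), flag = "unestimable")
  if (length(t) < min_points || length(unique(t)) < 2L) {
    class(out) <- "halflife_fit"
    return(out)
  }
  fit <- lm(log(a) ~ t)
  k <- -unname(coef(fit)[2])
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- list(
    k = k,
    t_half_h = if (k > 0) log(2) / k else Inf,
    se_k = se, r_squared = r2, n_points = length(t),
    flag = if (k > 0) "ok" else "stable"
  )
  class(out) <- "halflife_fit"
  out
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("<halflife_fit> t1/2 = %s h (k = %.4g /h, SE %.3g, R2 %.3f, n = %d, %s)\n",
              format(round(x$t_half_h, 2)), x$k, x$se_k, x$r_squared,
              x$n_points, x$flag))
  invisible(x)
}

#' Fit half-lives for every gene/fraction/condition stratum of a Ct table
#'
#' Convenience wrapper chaining [relative_abundance()] and [fit_halflife()].
#'
#' @inheritParams relative_abundance
#' @inheritParams fit_halflife
#' @return tibble (gene, fraction, condition, k, t_half_h, se_k, r_squared,
#'   n_points, flag).
#' @export
fit_halflives <- function(ct_table,
                          reference_genes = c("HPRT1", "SNRNP200", "ZMYM4"),
                          min_points = 4, floor_frac = 0.01) {
  relative_abundance(ct_table, reference_genes) |>
    group_by(.data$gene, .data$fraction, .data$condition) |>
    summarise(fit = list(fit_halflife(.data$timepoint_h, .data$rel_abundance,
                                      min_points, floor_frac)),
              .groups = "drop") |>
    mutate(k = map_dbl(fit, "k"), t_half_h = map_dbl(fit, "t_half_h"),
           se_k = map_dbl(fit, "se_k"), r_squared = map_dbl(fit, "r_squared"),
           n_points = map_int(fit, "n_points"), flag = map_chr(fit, "flag")) |>
    select(-"fit")
}

#' Compare two half-life fits
#'
#' Ratio of half-lives (`b` over `a`) and a two-sided z-test on the decay
#' rates using the regression standard errors.
#'
#' @param a,b `halflife_fit` objects.
#' @return tibble (ratio, z, pvalue, flag).
#' @export
compare_halflife <- function(a, b) {
  stopifnot(inherits(a, "halflife_fit"), inherits(b, "halflife_fit"))
  if (a$flag == "unestimable" || b$flag == "unestimable" ||
      !is.finite(a$t_half_h) || !is.finite(b$t_half_h)) {
    return(tibble(ratio = NA_real_, z = NA_real_, pvalue = NA_real_,
                  flag = "not_comparable"))
  }
  z <- (a$k - b$k) / sqrt(a$se_k^2 + b$se_k^2)
  tibble(ratio = b$t_half_h / a$t_half_h, z = z,
         pvalue = min(1, 2 * pnorm(-abs(z))), flag = "ok")
}

#' Check actinomycin-D transcription arrest from pre-mRNA levels
#'
#' Verifies that nuclear pre-mRNA abundance collapses after treatment in each
#' condition: the mean relative abundance of the pre-mRNA species at the
#' first post-treatment timepoint must drop below `max_residual_frac`.
#'
#' @param ct_table Ct table containing the pre-mRNA measurements.
#' @param premrna_genes names of the pre-mRNA assays in `gene`.
#' @param reference_genes reference genes for normalization.
#' @param max_residual_frac pass threshold on residual abundance
#'   (default 0.5).
#' @return tibble (condition, residual_frac, arrested).
#' @export
check_transcription_arrest <- function(ct_table, premrna_genes,
                                       reference_genes = c("HPRT1", "SNRNP200", "ZMYM4"),
                                       max_residual_frac = 0.5) {
  ra <- relative_abundance(ct_table, reference_genes) |>
    filter(.data$gene %in% premrna_genes)
  if (!nrow(ra)) abort("no pre-mRNA rows found")
  tps <- sort(unique(ra$timepoint_h))
  if (length(tps) < 2L) abort("need a post-treatment timepoint")
  t1 <- tps[2]
  ra |>
    filter(.data$timepoint_h == t1) |>
    group_by(.data$condition) |>
    summarise(residual_frac = mean(.data$rel_abundance), .groups = "drop") |>
    mutate(arrested = .data$residual_frac < max_residual_frac)
}
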