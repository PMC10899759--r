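#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_line
#'   geom_hline labs scale_color_manual theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a standard curve
#' @param x a `standard_curve`.
#' @param ... unused.
#' @return one-row tibble with term estimates (intercept, slope).
#' @export
tidy.standard_curve <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"), estimate = co[, 1],
         std_error = co[, 2], statistic = co[, 3], p_value = co[, 4])
}

#' @rdname tidy.standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_points = nrow(x$points))
}

#' Tidy a half-life fit
#' @param x a `halflife_fit`.
#' @param ... unused.
#' @return one-row tibble (k, t_half_h, se_k, r_squared, n_points, flag).
#' @export
tidy.halflife_fit <- function(x, ...) {
  tibble(k = x$k, t_half_h = x$t_half_h, se_k = x$se_k,
         r_squared = x$r_squared, n_points = x$n_points, flag = x$flag)
}

#' @rdname tidy.halflife_fit
#' @export
glance.halflife_fit <- function(x, ...) tidy(x)

#' Volcano plot of a differential-expression result
#' @param object a `de_result`.
#' @param fdr_threshold highlight threshold.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, fdr_threshold = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      .data$fdr < fdr_threshold & .data$log2fc > 0 ~ "up",
      .data$fdr < fdr_threshold & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot(df, aes(.data$log2fc, -log10(.data$pvalue), color = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_color_manual(values = c(up = "#2166ac", down = "#b2182b", ns = "grey70")) +
    labs(x = "log2 fold change (high vs low density)",
         y = "-log10 p", color = NULL) +
    theme_minimal()
}

#' Exon-intron split plot
#'
#' Intronic versus exonic log2 fold change with the best-fit line;
#' post-transcriptionally regulated genes sit above the line.
#'
#' @param object an `eisa_result` (ideally after [classify_regulation()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eisa_result <- function(object, ...) {
  df <- as_tibble(object)
  if (!"class" %in% names(df)) df$class <- "unclassified"
  p <- ggplot(df, aes(.data$d_intron, .data$d_exon, color = .data$class)) +
    geom_point(size = 0.9, alpha = 0.8) +
    labs(x = "log2 FC intronic (transcription)",
         y = "log2 FC exonic (mature mRNA)", color = NULL) +
    theme_minimal()
  fl <- attr(object, "fit_line")
  if (!is.null(fl)) {
    p <- p + geom_abline(intercept = fl["intercept"], slope = fl["slope"],
                         linetype = 2, color = "grey40")
  }
  p
}

#' Standard-curve plot
#' @param object a `standard_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot(object$points, aes(.data$mass_ng, .data$intensity_au)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                color = "#2166ac") +
    labs(x = "mass (ng)", y = "intensity (AU)") +
    theme_minimal()
}

#' Decay-course plot
#'
#' Relative abundance (log scale) over time for each gene/fraction/condition
#' stratum of a Ct table.
#'
#' @param ct_table tibble as in [relative_abundance()].
#' @param reference_genes reference gene names.
#' @return a ggplot.
#' @export
plot_decay <- function(ct_table,
                       reference_genes = c("HPRT1", "SNRNP200", "ZMYM4")) {
  ra <- relative_abundance(ct_table, reference_genes)
  ggplot(ra, aes(.data$timepoint_h, .data$rel_abundance,
                 color = .data$condition)) +
    geom_point(size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(fraction ~ gene) +
    labs(x = "time after actinomycin D (h)", y = "relative abundance") +
    theme_minimal()
}
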