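#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols rename
#'   distinct pull across n row_number desc if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap walk
#' @importFrom stats lm coef pchisq pnorm rnorm rpois rnbinom runif quantile
#'   p.adjust setNames var median complete.cases
#' @importFrom utils head tail
NULL

# Exact SI Avogadro constant (mol^-1).
AVOGADRO <- 6.02214076e23

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw from sub-seeds at fixed offsets of a single
#' master seed, so each simulated file is individually reproducible and the
#' whole dataset is byte-identical under a fixed `rng_seed`.
#'
#' @param seed master integer seed.
#' @param offset fixed non-negative integer offset for the stage.
#' @return an integer seed below 2^31.
#' @keywords internal
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

geo_mean <- function(x) exp(mean(log(x)))

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    abort(sprintf("`%s` must be a single %s integer, got %s",
                  name, if (positive) "positive" else "non-negative",
                  paste(x, collapse = ",")))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Counts tibble helpers: first column is the feature id, remaining columns are
# samples. Used by every matrix-consuming stage.
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2L)
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) abort("count matrix has negative entries")
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1]])
  m
}

matrix_to_counts <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_col := rownames(m)), out)
}

check_design <- function(design, samples) {
  stopifnot(is.data.frame(design), all(c("sample", "condition") %in% names(design)))
  missing <- setdiff(samples, design$sample)
  if (length(missing)) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  invisible(design)
}
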