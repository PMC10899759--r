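#' Simulate exonic, intronic and small-RNA count matrices
#'
#' Counts are negative-binomial with `var = mu + phi * mu^2` (Poisson when
#' `phi = 0`). Candidate genes at high density have their intronic mean
#' multiplied by `2^tx_effect_log2` and their exonic mean by
#' `2^(tx_effect_log2 + ptx_effect_log2)`, emulating regulation that acts
#' over and above transcription. Expected column sums equal the library
#' size. All miRNAs shift globally by `2^mirna_global_log2fc` at high
#' density (small-RNA library sizes grow accordingly; composition is
#' unchanged).
#'
#' @param cfg a [sim_config()].
#' @param annotation a [simulate_annotation()] result.
#' @param truth a [make_ground_truth()] result.
#' @param mirnome a [simulate_mirnome()] result.
#' @return list with tibbles `exonic`, `intronic`, `smallrna` (first column
#'   id, then samples) and `design` (sample, condition).
#' @export
simulate_counts <- function(cfg, annotation, truth, mirnome) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (cfg$library_size <= 0) abort("library_size must be positive")
  withr::with_seed(sub_seed(cfg$rng_seed, 4L), {
    genes <- annotation$genes$gene_id
    reps <- cfg$n_replicates
    samples <- c(sprintf("low_%d", seq_len(reps)), sprintf("high_%d", seq_len(reps)))
    design <- tibble(sample = samples,
                     condition = rep(c("low", "high"), each = reps))
    eff <- truth$effects[match(genes, truth$effects$gene_id), ]
    w <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 0.7)
    intron_frac <- runif(length(genes), 0.2, 0.5)
    draw <- function(mu) {
      if (cfg$nb_dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        rpois(length(mu), mu)
      }
    }
    # baseline (low-density) means sum to the library size; planted effects
    # at high density shift column totals slightly, as in real libraries
    make_matrix <- function(w_low, w_high) {
      cols <- map(seq_along(samples), function(j) {
        wj <- if (design$condition[j] == "low") w_low else w_high
        draw(wj / sum(w_low) * cfg$library_size)
      })
      m <- do.call(cbind, cols)
      dimnames(m) <- list(genes, samples)
      m
    }
    ex <- make_matrix(w, w * 2^(eff$tx_log2 + eff$ptx_log2))
    iw <- w * intron_frac
    intr <- make_matrix(iw, iw * 2^eff$tx_log2)

    mir <- mirnome$mirnas
    fam_w <- mirnome$families$weight[mir$family_id]
    share <- runif(nrow(mir), 0.3, 1)
    mir_w <- fam_w * share / stats::ave(share, mir$family_id, FUN = sum)
    mu_low <- mir_w / sum(mir_w) * cfg$library_size
    sm_cols <- map(seq_along(samples), function(j) {
      mu <- if (design$condition[j] == "low") mu_low else
        mu_low * 2^cfg$mirna_global_log2fc
      draw(mu)
    })
    sm <- do.call(cbind, sm_cols)
    dimnames(sm) <- list(mir$name, samples)
    list(
      exonic = matrix_to_counts(ex, "gene_id"),
      intronic = matrix_to_counts(intr, "gene_id"),
      smallrna = matrix_to_counts(sm, "mirna"),
      design = design
    )
  })
}
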