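test_that("2^-ddCt follows the textbook identities", {
  ct <- tibble::tibble(
    gene = rep(c("T", "HPRT1"), each = 2),
    fraction = "cytoplasm", condition = "low",
    timepoint_h = rep(c(0, 8), 2), replicate = 1L,
    ct = c(20, 21, 15, 15))  # target rises by 1 Ct, reference flat
  ra <- relative_abundance(ct, reference_genes = "HPRT1")
  expect_equal(ra$rel_abundance[ra$timepoint_h == 0], 1.0)
  expect_equal(ra$rel_abundance[ra$timepoint_h == 8], 0.5)
})

test_that("2^-ddCt equals an independent spreadsheet-style recomputation", {
  set.seed(19)
  grid <- tidyr::expand_grid(gene = c("T1", "T2"), timepoint_h = c(0, 4, 8),
                             replicate = 1:2)
  ct <- dplyr::bind_rows(
    grid |> dplyr::mutate(fraction = "cytoplasm", condition = "low",
                          ct = round(runif(dplyr::n(), 18, 26), 2)),
    tidyr::expand_grid(gene = c("R1", "R2"), timepoint_h = c(0, 4, 8),
                       replicate = 1:2) |>
      dplyr::mutate(fraction = "cytoplasm", condition = "low",
                    ct = round(runif(dplyr::n(), 14, 16), 2)))
  ra <- relative_abundance(ct, reference_genes = c("R1", "R2"))
  # independent chain: per row, dCt against the two references measured in
  # the same replicate/timepoint, then anchor at the mean dCt at t = 0
  for (i in sample(nrow(ra), 10)) {
    row <- ra[i, ]
    refs <- ct |> dplyr::filter(gene %in% c("R1", "R2"),
                                timepoint_h == row$timepoint_h,
                                replicate == row$replicate)
    dct <- row$ct - mean(refs$ct)
    d0 <- vapply(1:2, function(r) {
      refs0 <- ct |> dplyr::filter(gene %in% c("R1", "R2"), timepoint_h == 0,
                                   replicate == r)
      tgt0 <- ct |> dplyr::filter(gene == row$gene, timepoint_h == 0,
                                  replicate == r)
      tgt0$ct - mean(refs0$ct)
    }, numeric(1))
    expect_equal(row$rel_abundance, 2^-(dct - mean(d0)))
  }
  # rows lacking a reference measurement are dropped
  ct_miss <- ct |> dplyr::filter(!(gene %in% c("R1", "R2") & timepoint_h == 8))
  expect_message(ra2 <- relative_abundance(ct_miss, c("R1", "R2")), "dropping")
  expect_false(any(ra2$timepoint_h == 8))
})

test_that("half-life fitting is exact on geometric series and flags plateaus", {
  fit <- fit_halflife(c(0, 8, 16, 24), c(1, 0.5, 0.25, 0.125))
  expect_equal(fit$t_half_h, 8, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- fit_halflife(c(0, 8, 16, 24), rep(2, 4))
  expect_true(is.infinite(flat$t_half_h))
  expect_equal(flat$flag, "stable")
  few <- fit_halflife(c(0, 8), c(1, 0.5))
  expect_equal(few$flag, "unestimable")
  # invariant to overall rescaling of the abundances
  a <- c(1, 0.6, 0.3, 0.2, 0.1)
  t <- c(0, 4, 8, 12, 16)
  expect_equal(fit_halflife(t, a)$k, fit_halflife(t, 37 * a)$k)
  # plateau points below the floor are excluded
  withfloor <- fit_halflife(c(0, 8, 16, 24, 48), c(1, 0.5, 0.25, 0.125, 0.001))
  expect_equal(withfloor$n_points, 4L)
  expect_equal(withfloor$t_half_h, 8, tolerance = 1e-12)
})

test_that("half-life comparison reports exact ratios and a calibrated z-test", {
  f1 <- fit_halflife(c(0, 6, 12, 18, 24), 2^(-c(0, 6, 12, 18, 24) / 6))
  f2 <- fit_halflife(c(0, 6, 12, 18, 24), 2^(-c(0, 6, 12, 18, 24) / 12))
  cmp <- compare_halflife(f1, f2)
  expect_equal(cmp$ratio, 2, tolerance = 1e-9)
  same <- compare_halflife(f1, f1)
  expect_equal(same$ratio, 1)
  expect_equal(same$pvalue, 1)
  inf <- fit_halflife(c(0, 6, 12, 18, 24), rep(1, 5))
  expect_equal(compare_halflife(f1, inf)$flag, "not_comparable")
  # null calibration: equal half-lives give uniform p-values
  pv <- purrr::map_dbl(1:100, function(s) {
    hl <- tibble::tibble(gene = "T", fraction = "cytoplasm",
                         condition = c("low", "high"), t_half_h = 9)
    cfg <- sim_config(n_genes = 5, decay_halflives_h = hl, ct_noise_sd = 0.2,
                      rng_seed = 3000 + s)
    fits <- fit_halflives(simulate_decay(cfg)) |>
      dplyr::group_split(condition)
    a <- fits[[1]]; b <- fits[[2]]
    fa <- list(k = a$k, se_k = a$se_k, t_half_h = a$t_half_h, flag = a$flag)
    fb <- list(k = b$k, se_k = b$se_k, t_half_h = b$t_half_h, flag = b$flag)
    class(fa) <- class(fb) <- "halflife_fit"
    compare_halflife(fa, fb)$pvalue
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("transcription arrest is detected per condition", {
  base <- tidyr::expand_grid(timepoint_h = c(0, 1, 2), replicate = 1:2,
                             condition = c("low", "high"))
  pre <- base |> dplyr::mutate(
    gene = "preT", fraction = "nucleus",
    ct = 20 + dplyr::case_when(
      timepoint_h == 0 ~ 0,
      condition == "low" ~ 3.5,     # drops to ~9% by t = 1
      TRUE ~ 0))                    # no arrest at high density
  refs <- base |> dplyr::mutate(gene = "HPRT1", fraction = "nucleus", ct = 15)
  out <- check_transcription_arrest(dplyr::bind_rows(pre, refs), "preT",
                                    reference_genes = "HPRT1")
  expect_true(out$arrested[out$condition == "low"])
  expect_false(out$arrested[out$condition == "high"])
  flat <- dplyr::bind_rows(
    pre |> dplyr::mutate(ct = 20), refs)
  out2 <- check_transcription_arrest(flat, "preT", reference_genes = "HPRT1")
  expect_false(any(out2$arrested))
})
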