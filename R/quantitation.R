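#' Fit a densitometry standard curve
#'
#' Ordinary least-squares fit of band intensity against loaded recombinant
#' protein mass across a dilution series.
#'
#' @param points tibble with columns `mass_ng` and `intensity_au`
#'   (>= 3 distinct masses).
#' @return object of class `standard_curve` wrapping the `lm` fit, with
#'   `slope` (AU/ng), `intercept` (AU) and `r_squared`.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(all(c("mass_ng", "intensity_au") %in% names(points)))
  if (length(unique(points$mass_ng)) < 3L) {
    abort("standard curve needs >= 3 distinct masses")
  }
  fit <- lm(intensity_au ~ mass_ng, data = points)
  structure(
    list(fit = fit, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         mass_range = range(points$mass_ng), points = as_tibble(points)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> intensity = %.4g * mass_ng + %.4g (R2 %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Absolute protein copies per cell from band intensity
#'
#' Inverts the standard curve to a loaded mass, converts to molecule count
#' with the (exact SI) Avogadro constant, and divides by the number of cells
#' loaded (`cells_per_ul * loaded_volume_ul`). Intensities below the curve
#' intercept clip to zero copies with a flag; intensities outside the
#' calibrated mass range are flagged as extrapolated.
#'
#' @param intensity_au band intensity (vectorized).
#' @param curve a [fit_standard_curve()] object.
#' @param cells_per_ul lysate cell density (default 10,000 cells/ul).
#' @param loaded_volume_ul lysate volume loaded on the lane.
#' @param molar_mass_g_per_mol protein molar mass.
#' @return tibble (intensity_au, mass_ng, copies_per_cell, flag).
#' @examples
#' # 10 ng of a 100 kDa protein over 1e6 cells -> ~6e4 copies/cell
#' sc <- fit_standard_curve(tibble::tibble(mass_ng = 1:3, intensity_au = 2 * (1:3)))
#' copies_per_cell(20, sc, cells_per_ul = 1e5, loaded_volume_ul = 10,
#'                 molar_mass_g_per_mol = 1e5)
#' @export
copies_per_cell <- function(intensity_au, curve, cells_per_ul = 10000,
                            loaded_volume_ul, molar_mass_g_per_mol) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) abort("standard curve has non-positive slope")
  mass_ng <- (intensity_au - curve$intercept) / curve$slope
  flag <- dplyr::case_when(
    mass_ng < 0 ~ "below_intercept",
    mass_ng < curve$mass_range[1] | mass_ng > curve$mass_range[2] ~ "extrapolated",
    TRUE ~ "ok"
  )
  mass_ng <- pmax(mass_ng, 0)
  molecules <- mass_ng * 1e-9 / molar_mass_g_per_mol * AVOGADRO
  tibble(
    intensity_au = intensity_au, mass_ng = mass_ng,
    copies_per_cell = molecules / (cells_per_ul * loaded_volume_ul),
    flag = flag
  )
}

#' Nuclear:cytoplasmic copy-number ratio
#'
#' @param nucleus,cytoplasm copies per cell in each compartment (scalars or
#'   single-row [copies_per_cell()] tibbles).
#' @param whole_cell optional whole-cell copies per cell; when given, the
#'   conservation residual `(nucleus + cytoplasm - whole_cell) / whole_cell`
#'   is reported (never enforced).
#' @return tibble (nucleus_copies, cytoplasm_copies, ratio,
#'   conservation_residual).
#' @export
compartment_ratio <- function(nucleus, cytoplasm, whole_cell = NULL) {
  pick <- function(x) if (is.data.frame(x)) x$copies_per_cell[1] else x[1]
  n <- pick(nucleus); c_ <- pick(cytoplasm)
  if (c_ == 0) abort("cytoplasmic copies are zero: ratio undefined")
  w <- if (is.null(whole_cell)) NA_real_ else pick(whole_cell)
  tibble(
    nucleus_copies = n, cytoplasm_copies = c_, ratio = n / c_,
    conservation_residual = if (is.na(w)) NA_real_ else (n + c_ - w) / w
  )
}

#' Scratch-assay migration rate
#'
#' Per-interval cell-front speed from wound widths: each of the two fronts
#' advances `(width(0) - width(t)) / 2` over time `t`, so the rate is
#' `(width(0) - width(t)) / (2 t)` in um/h. Negative closure (wound wider
#' than at start) clips to rate 0 with a flag.
#'
#' @param series tibble with columns `timepoint_h` (strictly increasing from
#'   0) and `width_um` (>= 0).
#' @return tibble of per-interval rates plus attribute `mean_rate`; also
#'   returned as the `mean_rate_um_per_h` column repeated for convenience.
#' @export
migration_rate <- function(series) {
  stopifnot(all(c("timepoint_h", "width_um") %in% names(series)))
  series <- series |> arrange(.data$timepoint_h)
  if (series$timepoint_h[1] != 0) abort("series must start at t = 0")
  if (is.unsorted(series$timepoint_h, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (any(series$width_um < 0)) abort("widths must be >= 0")
  if (nrow(series) < 2L) abort("need >= 2 timepoints")
  w0 <- series$width_um[1]
  out <- series |>
    filter(.data$timepoint_h > 0) |>
    mutate(
      closure_um = w0 - .data$width_um,
      rate_um_per_h = pmax(0, .data$closure_um) / (2 * .data$timepoint_h),
      flag = if_else(.data$closure_um < 0, "negative_closure", "ok")
    )
  if (all(out$closure_um < 0)) {
    warn("wound never narrower than at t = 0; rates all 0")
  }
  out$mean_rate_um_per_h <- mean(out$rate_um_per_h)
  out
}
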