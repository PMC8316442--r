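#' TEER normalization
#'
#' Blank-corrected, area-scaled transepithelial electrical resistance:
#' `(raw - blank_resistance) * well_area`, the standard reduction for a
#' 24-well Transwell plate (blank 100 ohm, insert area 0.33 cm^2). Readings
#' below the blank give negative values: these are kept and flagged, never
#' clipped, so suspect wells stay auditable.
#'
#' `teer_value()` is the vectorized arithmetic; `normalize_teer()` is the
#' data-frame interface, which also averages replicates per condition when a
#' `condition` column is present.
#'
#' @param raw Raw resistance reading(s), ohm (>= 0).
#' @param blank_resistance Blank-well resistance, ohm.
#' @param well_area Insert area, cm^2.
#' @return `teer_value()`: numeric, ohm * cm^2.
#' @export
#' @examples
#' teer_value(400)  # (400 - 100) * 0.33 = 99 ohm cm2
teer_value <- function(raw, blank_resistance = 100, well_area = 0.33) {
  if (any(raw < 0)) abort("Raw TEER readings must be non-negative.")
  if (blank_resistance < 0 || well_area <= 0) {
    abort("`blank_resistance` must be >= 0 and `well_area` > 0.")
  }
  (raw - blank_resistance) * well_area
}

#' @param data Data frame with a `raw_ohm` column; optional `condition`.
#' @rdname teer_value
#' @return `normalize_teer()`: the input tibble plus `teer_ohm_cm2` and
#'   `flagged` (TRUE where the reading fell below the blank). Per-condition
#'   replicate means, when available, are attached as
#'   `attr(x, "condition_means")`.
#' @export
normalize_teer <- function(data, blank_resistance = 100, well_area = 0.33) {
  stopifnot(is.data.frame(data), "raw_ohm" %in% names(data))
  out <- as_tibble(data) |>
    mutate(
      teer_ohm_cm2 = teer_value(.data$raw_ohm, blank_resistance, well_area),
      flagged = .data$raw_ohm < blank_resistance
    )
  if (any(out$flagged)) {
    warn(sprintf("%d TEER reading(s) below the blank: negative values flagged.",
                 sum(out$flagged)))
  }
  if ("condition" %in% names(out)) {
    attr(out, "condition_means") <- out |>
      group_by(.data$condition) |>
      summarise(mean_teer_ohm_cm2 = mean(.data$teer_ohm_cm2),
                n_wells = n(), .groups = "drop")
  }
  out
}

#' Mean fluorescence per cell
#'
#' Field-of-view mean gray value normalized by the number of cells in the
#' field.
#'
#' @param mean_gray_value Field mean intensity (>= 0).
#' @param n_cells Cells in the field (>= 1).
#' @return Intensity per cell.
#' @export
fluorescence_per_cell <- function(mean_gray_value, n_cells) {
  if (any(n_cells < 1)) abort("`n_cells` must be >= 1.")
  if (any(mean_gray_value < 0)) abort("`mean_gray_value` must be >= 0.")
  mean_gray_value / n_cells
}

#' Fraction of marker-positive cells
#'
#' @param n_positive Marker-positive cell count.
#' @param n_cells Total cell count (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
positive_fraction <- function(n_positive, n_cells) {
  if (any(n_cells < 1)) abort("`n_cells` must be >= 1.")
  if (any(n_positive < 0) || any(n_positive > n_cells)) {
    abort("`n_positive` must lie in [0, n_cells].")
  }
  n_positive / n_cells
}

#' Elastic modulus from shear storage modulus
#'
#' Rubber elasticity: `E = 2 * (1 + nu) * G'`. For an incompressible
#' hydrogel (`nu = 0.5`) this reduces to `E = 3 G'`, so a gel with
#' `G' = 1 kPa` is the familiar "3 kPa" soft substrate.
#'
#' @param g_prime Shear storage modulus G', kPa (> 0).
#' @param poisson_ratio Poisson's ratio in `[0, 0.5]`.
#' @return Elastic modulus E, kPa.
#' @export
modulus_from_storage <- function(g_prime, poisson_ratio = 0.5) {
  if (any(g_prime <= 0)) abort("`g_prime` must be positive.")
  if (any(poisson_ratio < 0) || any(poisson_ratio > 0.5)) {
    abort("`poisson_ratio` must lie in [0, 0.5].")
  }
  2 * (1 + poisson_ratio) * g_prime
}
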