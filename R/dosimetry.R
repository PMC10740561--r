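# Dose <-> fluence <-> ion-count conversions for high-LET ions.
#
# One ion of LET L (keV/um) crossing a unit-density (water-equivalent) target
# of area S (um^2) deposits a dose of L * K_GY_UM3_PER_KEV / S gray, using
# 1 keV = 1.602e-16 J and 1 um^3 of unit-density material = 1e-15 kg, i.e.
# K = 1.602e-16 / 1e-15 = 0.1602 Gy um^3 / keV.

#' @keywords internal
K_GY_UM3_PER_KEV <- 0.1602

# round half away from zero, to a natural number (x >= 0)
round_half_up <- function(x) floor(x + 0.5)

#' Ion count for a prescribed absorbed dose
#'
#' Number of ions `P` that must traverse a region of area `S` so that the
#' average absorbed dose equals `D`:
#' `P = round(D * S / (L * 0.1602))`, rounded to the nearest natural number
#' (half away from zero). Because `P` is discrete, the realized dose is
#' quantized; see [quantization_report()].
#'
#' @param dose Absorbed dose `D` in Gy (>= 0).
#' @param area Region area `S` in um^2 (> 0).
#' @param let LET `L` in keV/um (> 0).
#' @return Integer ion count `P` (possibly 0).
#' @examples
#' ion_count(3.2, 4, 80) # one ion in a 2 x 2 um block
#' @export
ion_count <- function(dose, area, let) {
  if (!is.finite(dose) || dose < 0) {
    rlang::abort("dose must be >= 0 Gy", class = "ionpaint_dose_error")
  }
  if (!is.finite(area) || area <= 0) {
    rlang::abort("area must be > 0 um^2", class = "ionpaint_dose_error")
  }
  if (!is.finite(let) || let <= 0) {
    rlang::abort("LET must be > 0 keV/um", class = "ionpaint_dose_error")
  }
  as.integer(round_half_up(dose * area / (let * K_GY_UM3_PER_KEV)))
}

#' Fluence for a prescribed dose
#'
#' The (real-valued) number of ions crossing 1 um^2 when a unit-density target
#' receives dose `D` from ions of LET `L`: `F = D / (L * 0.1602)`.
#'
#' @inheritParams ion_count
#' @return Fluence in ions/um^2.
#' @examples
#' fluence(100, 80) # ~7.8 ions/um^2
#' @export
fluence <- function(dose, let) {
  if (!is.finite(dose) || dose < 0) {
    rlang::abort("dose must be >= 0 Gy", class = "ionpaint_dose_error")
  }
  if (!is.finite(let) || let <= 0) {
    rlang::abort("LET must be > 0 keV/um", class = "ionpaint_dose_error")
  }
  dose / (let * K_GY_UM3_PER_KEV)
}

#' Absorbed dose deposited in a block by n ions
#'
#' The exactly linear inverse of [ion_count()] at fixed geometry:
#' `dose = n * L * 0.1602 / S_block`. No intermediate value exists between
#' consecutive `n` -- the dose quantum of discrete heavy-ion irradiation.
#'
#' @param n Integer ion count (>= 0).
#' @param let LET in keV/um (> 0).
#' @param block_area Block area in um^2 (> 0).
#' @return Dose in Gy.
#' @examples
#' block_dose(1, 80, 4) # 3.204 Gy: one 80 keV/um ion in a 2 x 2 um block
#' block_dose(2, 80, 4) # 6.408 Gy: doses come only in whole-ion steps
#' @export
block_dose <- function(n, let, block_area) {
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n))) {
    rlang::abort("n must be a non-negative integer ion count",
                 class = "ionpaint_dose_error")
  }
  if (!is.finite(let) || let <= 0 || !is.finite(block_area) || block_area <= 0) {
    rlang::abort("LET and block area must be > 0", class = "ionpaint_dose_error")
  }
  n * let * K_GY_UM3_PER_KEV / block_area
}

#' Evenly distribute ions over pixels
#'
#' Splits a total ion count `P` over `N` pixels into a whole number of ions
#' per pixel plus a remainder that cannot be distributed evenly:
#' `base = floor(P / N)`, `remainder = P - base * N` (`0 <= remainder < N`).
#' The remainder ions are the ones the placement methods of [plan_hits()]
#' spread over the region.
#'
#' @param p Total ion count (>= 0).
#' @param n_pixels Number of pixels `N` (>= 1).
#' @return A list with integer fields `base` and `remainder`.
#' @examples
#' decompose_per_pixel(13, 5) # base 2, remainder 3
#' @export
decompose_per_pixel <- function(p, n_pixels) {
  if (!is.finite(p) || p < 0 || p != floor(p)) {
    rlang::abort("p must be a non-negative integer", class = "ionpaint_dose_error")
  }
  if (!is.finite(n_pixels) || n_pixels < 1 || n_pixels != floor(n_pixels)) {
    rlang::abort("n_pixels must be an integer >= 1", class = "ionpaint_dose_error")
  }
  base <- p %/% n_pixels
  list(base = as.integer(base), remainder = as.integer(p - base * n_pixels))
}

#' Dose-quantization report for planned regions
#'
#' For each region, the integer ion count, the dose actually realizable with
#' that count, and the relative quantization error. Because the ion count is a
#' natural number, the realized dose moves in steps of one dose-per-ion
#' (`L * 0.1602 / S`); regions whose prescription falls between steps incur an
#' unavoidable error, flagged with a warning when it exceeds 5%.
#'
#' @param regions Regions tibble (see [region()]).
#' @param grid A [calibrated_grid()].
#' @param beam A [beam_parameters()].
#' @return A tibble with one row per region: `label`, `dose`, `area_um2`,
#'   `n_pixels`, `ions`, `realized_dose`, `rel_error`, `flagged`.
#' @export
quantization_report <- function(regions, grid, beam) {
  stopifnot(inherits(grid, "calibrated_grid"), inherits(beam, "beam_parameters"))
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    mask <- regions$mask[[i]]
    dose <- regions$dose[i]
    s <- mask_area(mask, grid)
    p <- if (dose > 0) ion_count(dose, s, beam$let) else 0L
    realized <- if (s > 0) block_dose(p, beam$let, s) else 0
    rel <- if (dose > 0) abs(realized - dose) / dose else 0
    tibble::tibble(
      label = regions$label[i], dose = dose, area_um2 = s,
      n_pixels = nrow(mask), ions = p, realized_dose = realized,
      rel_error = rel, flagged = rel > 0.05
    )
  })
}
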