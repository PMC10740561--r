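#' Calibrated pixel grid
#'
#' The common coordinate frame for all planning operations: a lattice of
#' `width_px` x `height_px` camera pixels with an isotropic physical
#' calibration in micrometres per pixel. Pixel `(col = i, row = j)` (0-based)
#' spans the half-open square `[i, i+1) x [j, j+1)` in pixel units; its centre
#' is `(i + 0.5, j + 0.5)` and physical coordinates are pixel coordinates
#' multiplied by `scale`.
#'
#' Defaults follow a targeting-microscope screen of 480 pixels in width and
#' 640 pixels in height, where 180 pixels correspond to 228.9 um.
#'
#' @param width_px Number of pixel columns (>= 1).
#' @param height_px Number of pixel rows (>= 1).
#' @param scale Physical size of one pixel in um (> 0).
#' @return An object of class `calibrated_grid`.
#' @examples
#' g <- calibrated_grid()
#' g$scale * 180 # 228.9 um field calibration
#' @export
calibrated_grid <- function(width_px = 480L, height_px = 640L,
                            scale = 228.9 / 180) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px < 1L || is.na(height_px) || height_px < 1L) {
    rlang::abort("grid dimensions must be integers >= 1", class = "ionpaint_grid_error")
  }
  if (!is.finite(scale) || scale <= 0) {
    rlang::abort("scale must be a positive um/pixel factor", class = "ionpaint_grid_error")
  }
  structure(
    list(width_px = width_px, height_px = height_px, scale = scale),
    class = "calibrated_grid"
  )
}

#' @export
print.calibrated_grid <- function(x, ...) {
  cat(sprintf(
    "<calibrated_grid> %d x %d px at %.6g um/px (%.4g x %.4g um)\n",
    x$width_px, x$height_px, x$scale,
    x$width_px * x$scale, x$height_px * x$scale
  ))
  invisible(x)
}

#' Beam parameters
#'
#' Physical description of the focused ion beam: species label, linear energy
#' transfer (LET) at the sample surface, and the focused spot diameter. The
#' spot diameter is used by the detector simulator as the support of the
#' landing-position spread.
#'
#' @param ion Free-text ion species label, e.g. `"carbon 26.6 MeV/u"`.
#' @param let LET in keV/um (> 0).
#' @param spot_um Focused beam spot diameter in um (>= 0).
#' @return An object of class `beam_parameters`.
#' @examples
#' beam_parameters("carbon 26.6 MeV/u", let = 80, spot_um = 5)
#' @export
beam_parameters <- function(ion = "carbon 26.6 MeV/u", let = 80, spot_um = 5) {
  if (!is.finite(let) || let <= 0) {
    rlang::abort("LET must be > 0 keV/um", class = "ionpaint_beam_error")
  }
  if (!is.finite(spot_um) || spot_um < 0) {
    rlang::abort("spot diameter must be >= 0 um", class = "ionpaint_beam_error")
  }
  structure(list(ion = ion, let = let, spot_um = spot_um),
            class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf("<beam_parameters> %s, LET %.4g keV/um, spot %.4g um\n",
              x$ion, x$let, x$spot_um))
  invisible(x)
}

# --- internal mask helpers ---------------------------------------------------

# A mask is a tibble with 0-based integer columns `col` (x pixel index) and
# `row` (y pixel index), each pixel inside the grid bounds.

new_mask <- function(col, row) {
  tibble::tibble(col = as.integer(col), row = as.integer(row))
}

assert_mask <- function(mask, grid = NULL, arg = "mask") {
  if (!is.data.frame(mask) || !all(c("col", "row") %in% names(mask))) {
    rlang::abort(sprintf("`%s` must be a data frame with `col` and `row` columns", arg),
                 class = "ionpaint_mask_error")
  }
  if (!is.null(grid)) {
    bad <- mask$col < 0L | mask$col >= grid$width_px |
      mask$row < 0L | mask$row >= grid$height_px
    if (any(bad)) {
      rlang::abort(sprintf("`%s` contains pixels outside the grid bounds", arg),
                   class = "ionpaint_mask_error")
    }
  }
  invisible(mask)
}

# unique linear id of each pixel (row-major)
pixel_id <- function(mask, grid) {
  as.numeric(mask$row) * grid$width_px + as.numeric(mask$col)
}

# logical raster [height_px rows x width_px cols] from a mask tibble
mask_to_matrix <- function(mask, grid) {
  m <- matrix(FALSE, nrow = grid$height_px, ncol = grid$width_px)
  if (nrow(mask)) m[cbind(mask$row + 1L, mask$col + 1L)] <- TRUE
  m
}

matrix_to_mask <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  new_mask(col = idx[, 2] - 1L, row = idx[, 1] - 1L)
}
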