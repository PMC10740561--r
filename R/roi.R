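#' Shape specifications for irradiation targets
#'
#' Programmatic equivalents of the drawing tools used to outline a target on
#' the microscope image: axis-aligned rectangles, ellipses, polygons and
#' closed cardinal splines. All control points are in pixel coordinates on a
#' [calibrated_grid()].
#'
#' @param x0,y0,x1,y1 Rectangle corners in pixel units (any two opposite
#'   corners).
#' @param cx,cy Ellipse centre in pixel units.
#' @param a,b Ellipse semi-axes along x and y, in pixels (> 0).
#' @param points A two-column matrix (or data frame) of vertex / control-point
#'   pixel coordinates. Polygons and splines are closed implicitly.
#' @param tension Cardinal-spline tension in `[0, 1]`; 0 gives a Catmull-Rom
#'   spline, 1 degenerates to the control polygon.
#' @return A `shape_spec` object.
#' @name shape_spec
#' @examples
#' shape_rectangle(0, 0, 10, 10)
#' shape_ellipse(240, 320, a = 90, b = 90)
NULL

new_shape <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "shape_spec")
}

#' @rdname shape_spec
#' @export
shape_rectangle <- function(x0, y0, x1, y1) {
  stopifnot(is.finite(c(x0, y0, x1, y1)))
  new_shape("rectangle", x0 = min(x0, x1), y0 = min(y0, y1),
            x1 = max(x0, x1), y1 = max(y0, y1))
}

#' @rdname shape_spec
#' @export
shape_ellipse <- function(cx, cy, a, b = a) {
  stopifnot(is.finite(c(cx, cy, a, b)))
  if (a <= 0 || b <= 0) {
    rlang::abort("ellipse semi-axes must be > 0", class = "ionpaint_shape_error")
  }
  new_shape("ellipse", cx = cx, cy = cy, a = a, b = b)
}

#' @rdname shape_spec
#' @export
shape_polygon <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3 || !all(is.finite(points))) {
    rlang::abort("polygon needs >= 3 finite (x, y) vertices",
                 class = "ionpaint_shape_error")
  }
  new_shape("polygon", points = unname(points))
}

#' @rdname shape_spec
#' @export
shape_cardinal_spline <- function(points, tension = 0) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3 || !all(is.finite(points))) {
    rlang::abort("cardinal spline needs >= 3 finite control points",
                 class = "ionpaint_shape_error")
  }
  if (!is.finite(tension) || tension < 0 || tension > 1) {
    rlang::abort("spline tension must be in [0, 1]", class = "ionpaint_shape_error")
  }
  new_shape("cardinal_spline", points = unname(points), tension = tension)
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s\n", x$kind))
  invisible(x)
}

# Sample a closed cardinal spline into a dense polygon. Tangent at control
# point i is s * (p[i+1] - p[i-1]) with s = (1 - tension) / 2 (cyclic), and
# each interval is rendered with a cubic Hermite segment.
spline_to_polygon <- function(points, tension, samples_per_interval = 16L) {
  n <- nrow(points)
  s <- (1 - tension) / 2
  prv <- points[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- points[c(seq_len(n)[-1], 1), , drop = FALSE]
  tang <- s * (nxt - prv)
  t <- seq(0, 1, length.out = samples_per_interval + 1L)[-(samples_per_interval + 1L)]
  h00 <- 2 * t^3 - 3 * t^2 + 1
  h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2
  h11 <- t^3 - t^2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    seg <- outer(h00, points[i, ]) + outer(h10, tang[i, ]) +
      outer(h01, points[j, ]) + outer(h11, tang[j, ])
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

#' Rasterize a shape onto a calibrated grid
#'
#' Scan-converts a [shape_spec] to a pixel mask using the pixel-centre
#' inclusion rule: a pixel belongs to the shape iff its centre
#' `(i + 0.5, j + 0.5)` lies inside the closed contour. The mask is clipped to
#' the grid bounds. Rasterization is deterministic and idempotent.
#'
#' @param spec A [shape_spec].
#' @param grid A [calibrated_grid()].
#' @return A mask: a tibble with 0-based integer `col`, `row` pixel indices.
#' @examples
#' g <- calibrated_grid(100, 100, 1)
#' nrow(rasterize_shape(shape_rectangle(0, 0, 10, 10), g)) # 100 pixels
#' @export
rasterize_shape <- function(spec, grid) {
  stopifnot(inherits(spec, "shape_spec"), inherits(grid, "calibrated_grid"))
  mask <- switch(spec$kind,
    rectangle = rasterize_rectangle(spec, grid),
    ellipse = rasterize_ellipse(spec, grid),
    polygon = rasterize_polygon(spec$points, grid),
    cardinal_spline = rasterize_polygon(
      spline_to_polygon(spec$points, spec$tension), grid
    ),
    rlang::abort(sprintf("unknown shape kind '%s'", spec$kind),
                 class = "ionpaint_shape_error")
  )
  if (nrow(mask) == 0) {
    rlang::abort("degenerate shape: rasterizes to an empty mask",
                 class = "ionpaint_empty_mask_error")
  }
  mask
}

rasterize_rectangle <- function(spec, grid) {
  cols <- seq_len(grid$width_px) - 1L
  rows <- seq_len(grid$height_px) - 1L
  cols <- cols[cols + 0.5 > spec$x0 & cols + 0.5 < spec$x1]
  rows <- rows[rows + 0.5 > spec$y0 & rows + 0.5 < spec$y1]
  if (!length(cols) || !length(rows)) return(new_mask(integer(), integer()))
  new_mask(col = rep(cols, times = length(rows)),
           row = rep(rows, each = length(cols)))
}

rasterize_ellipse <- function(spec, grid) {
  cols <- (seq_len(grid$width_px) - 1L)
  rows <- (seq_len(grid$height_px) - 1L)
  cols <- cols[abs(cols + 0.5 - spec$cx) <= spec$a]
  rows <- rows[abs(rows + 0.5 - spec$cy) <= spec$b]
  if (!length(cols) || !length(rows)) return(new_mask(integer(), integer()))
  cx <- rep(cols, times = length(rows))
  ry <- rep(rows, each = length(cols))
  inside <- ((cx + 0.5 - spec$cx) / spec$a)^2 +
    ((ry + 0.5 - spec$cy) / spec$b)^2 <= 1
  new_mask(col = cx[inside], row = ry[inside])
}

rasterize_polygon <- function(points, grid) {
  # degenerate contour: zero enclosed area
  area2 <- abs(sum(points[, 1] * c(points[-1, 2], points[1, 2]) -
                     c(points[-1, 1], points[1, 1]) * points[, 2]))
  if (area2 < .Machine$double.eps * 100) return(new_mask(integer(), integer()))
  xr <- range(points[, 1]); yr <- range(points[, 2])
  cols <- seq_len(grid$width_px) - 1L
  rows <- seq_len(grid$height_px) - 1L
  cols <- cols[cols + 0.5 >= xr[1] & cols + 0.5 <= xr[2]]
  rows <- rows[rows + 0.5 >= yr[1] & rows + 0.5 <= yr[2]]
  if (!length(cols) || !length(rows)) return(new_mask(integer(), integer()))
  cx <- rep(cols, times = length(rows))
  ry <- rep(rows, each = length(cols))
  bnd <- rbind(points, points[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(cx + 0.5, ry + 0.5))
  new_mask(col = cx[inside], row = ry[inside])
}

#' Threshold a grayscale image into a mask
#'
#' Selects the pixels of a fluorescence (or any grayscale) image whose
#' intensity is greater than or equal to `threshold` -- the automatic
#' region-specification route, where a transgenic strain's fluorescence marks
#' the tissue to irradiate.
#'
#' @param image Numeric matrix `[height_px, width_px]` of intensities. An
#'   optional `bits` attribute (8 or 16) declares the representable range;
#'   8 bits (0-255) is assumed when absent.
#' @param threshold Inclusive intensity threshold; must lie within the image's
#'   representable range.
#' @return A mask tibble (`col`, `row`).
#' @export
binarize_image <- function(image, threshold) {
  stopifnot(is.matrix(image), is.numeric(image))
  bits <- attr(image, "bits") %||% 8L
  if (!is.finite(threshold) || threshold < 0 || threshold > 2^bits - 1) {
    rlang::abort(sprintf("threshold %s outside the %d-bit intensity range [0, %d]",
                         format(threshold), bits, 2L^bits - 1L),
                 class = "ionpaint_threshold_error")
  }
  matrix_to_mask(image >= threshold)
}

#' Partition an image into dose regions by brightness
#'
#' Bins every pixel of a grayscale image into `k = length(doses)` regions by
#' `k - 1` ascending intensity thresholds and assigns each region a prescribed
#' absorbed dose. Bins are half-open: a pixel of intensity `v` falls in region
#' `r` when `thresholds[r-1] <= v < thresholds[r]` (lowest bin open below, top
#' bin closed above), so the regions are pairwise disjoint and cover the image
#' exactly. Regions with dose 0 are retained but receive no ions when planned.
#'
#' @inheritParams binarize_image
#' @param thresholds Strictly ascending intensity thresholds (length `k - 1`).
#' @param doses Absorbed doses in Gy, one per region, lowest-brightness first.
#' @param labels Optional region labels; defaults to `band1..bandk`.
#' @return A regions tibble (see [region()]): columns `label`, `dose`, `mask`.
#' @examples
#' img <- matrix(rep(seq(0, 255, length.out = 100), each = 50), nrow = 50)
#' rg <- partition_by_brightness(img, c(64, 128, 192), c(0, 0.5, 1.5, 2.5))
#' rg$label
#' @export
partition_by_brightness <- function(image, thresholds, doses, labels = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(thresholds) && any(diff(thresholds) <= 0)) {
    rlang::abort("thresholds must be strictly ascending",
                 class = "ionpaint_threshold_error")
  }
  if (length(doses) != length(thresholds) + 1L) {
    rlang::abort("need exactly one dose per brightness bin (|doses| = |thresholds| + 1)",
                 class = "ionpaint_threshold_error")
  }
  if (any(doses < 0)) {
    rlang::abort("doses must be non-negative", class = "ionpaint_dose_error")
  }
  k <- length(doses)
  labels <- labels %||% paste0("band", seq_len(k))
  stopifnot(length(labels) == k)
  bin <- matrix(findInterval(image, thresholds) + 1L, nrow = nrow(image))
  # unlike user-drawn regions, brightness bins may legitimately be empty
  # (e.g. a constant image), so build rows without region()'s emptiness check
  purrr::map_dfr(seq_len(k), function(r) {
    tibble::tibble(label = labels[r], dose = doses[r],
                   mask = list(matrix_to_mask(bin == r)))
  })
}

#' Define an irradiation region
#'
#' A region couples a pixel mask with a label and a prescribed absorbed dose
#' in Gy. Regions are rows of a tibble with a `mask` list-column so that
#' multi-region plans compose with [dplyr::bind_rows()].
#'
#' @param label Region identifier (character scalar).
#' @param mask Mask tibble (`col`, `row`), e.g. from [rasterize_shape()].
#' @param dose Prescribed absorbed dose in Gy (>= 0).
#' @return A one-row tibble with columns `label`, `dose`, `mask`.
#' @export
region <- function(label, mask, dose) {
  assert_mask(mask)
  if (!is.finite(dose) || dose < 0) {
    rlang::abort("dose must be a finite non-negative Gy value",
                 class = "ionpaint_dose_error")
  }
  if (dose > 0 && nrow(mask) == 0) {
    rlang::abort(sprintf("region '%s': empty mask with a positive dose", label),
                 class = "ionpaint_empty_mask_error")
  }
  tibble::tibble(label = as.character(label), dose = dose,
                 mask = list(new_mask(mask$col, mask$row)))
}

#' Physical area of a mask
#'
#' The region area used in dosimetry: the pixel count times the calibrated
#' pixel area, `S = |mask| * scale^2` in um^2.
#'
#' @param mask Mask tibble.
#' @param grid A [calibrated_grid()].
#' @return Area in um^2.
#' @export
mask_area <- function(mask, grid) {
  assert_mask(mask, grid)
  nrow(mask) * grid$scale^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
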