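# Deterministic synthetic inputs emulating the published demonstration
# targets: a circular test field, a five-level brightness-graded logo, and
# stylized nematode organ shapes (pharynx bulbs, isthmus, gonad arms). The
# organ shapes are geometric proxies -- ellipses and thick curved bands --
# because the planner is shape-agnostic; they exercise convex, multi-component
# and elongated/concave masks without any anatomical modelling.

#' Centred circular mask
#'
#' The circular test field used to validate uniform filling: a disk of
#' `diameter_px` pixels centred on the grid, rasterized by pixel-centre
#' inclusion.
#'
#' @param grid A [calibrated_grid()].
#' @param diameter_px Disk diameter in pixels (> 0, at most the smaller grid
#'   dimension).
#' @return A mask tibble.
#' @examples
#' nrow(make_circle_mask(calibrated_grid(), 180)) # ~ pi * 90^2 pixels
#' @export
make_circle_mask <- function(grid, diameter_px = 180) {
  stopifnot(inherits(grid, "calibrated_grid"))
  if (!is.finite(diameter_px) || diameter_px <= 0) {
    rlang::abort("diameter must be > 0 pixels", class = "ionpaint_shape_error")
  }
  if (diameter_px > min(grid$width_px, grid$height_px)) {
    rlang::abort("diameter exceeds the grid", class = "ionpaint_shape_error")
  }
  rasterize_shape(
    shape_ellipse(grid$width_px / 2, grid$height_px / 2, a = diameter_px / 2),
    grid
  )
}

#' Synthetic brightness-gradient image
#'
#' A monotone grayscale ramp suitable for [partition_by_brightness()]: linear
#' (left-to-right) or radial (bright centre fading outward), 8-bit intensities.
#'
#' @param grid A [calibrated_grid()].
#' @param profile `"linear"` or `"radial"`.
#' @return An intensity matrix `[height_px, width_px]` with `bits = 8`.
#' @export
make_gradient_image <- function(grid, profile = c("linear", "radial")) {
  profile <- match.arg(profile)
  stopifnot(inherits(grid, "calibrated_grid"))
  w <- grid$width_px; h <- grid$height_px
  img <- if (profile == "linear") {
    matrix(rep(seq(0, 255, length.out = w), each = h), nrow = h)
  } else {
    cx <- w / 2; cy <- h / 2
    dx <- matrix(rep((seq_len(w) - 0.5) - cx, each = h), nrow = h)
    dy <- matrix(rep((seq_len(h) - 0.5) - cy, times = w), nrow = h)
    d <- sqrt(dx^2 + dy^2)
    matrix(round(255 * pmax(0, 1 - d / max(d))), nrow = h)
  }
  img <- round(img)
  attr(img, "bits") <- 8L
  img
}

# seed-stable uniform perturbation factor in [1 - amp, 1 + amp]
wobble <- function(n, amp = 0.05) 1 + stats::runif(n, -amp, amp)

#' Stylized nematode organ masks
#'
#' Deterministic organ-shaped target masks for exercising the planner on
#' realistic geometries:
#' \describe{
#'   \item{`pharynx`}{two elliptical bulbs (anterior and terminal) joined by a
#'     narrow isthmus band.}
#'   \item{`pharynx_no_isthmus`}{the two bulbs with the isthmus band removed
#'     -- exactly two connected components, the geometry used to spare the
#'     nerve ring around the isthmus.}
#'   \item{`anterior_bulb`, `terminal_bulb`}{single bulbs.}
#'   \item{`gonad`}{a thick U-shaped band whose bounding box spans more than
#'     one 480-px microscope field of view, emulating a target spread over
#'     two screens.}
#' }
#' Shapes receive small seed-driven size/position perturbations, so one seed
#' reproduces one mask bit-exactly.
#'
#' @param kind Organ kind (see above).
#' @param grid A [calibrated_grid()]; the gonad needs a grid at least
#'   960 px wide.
#' @param seed Integer seed for the shape perturbation.
#' @return A mask tibble with attribute `meta` (the generating parameters).
#' @export
make_worm_organ_mask <- function(kind = c("pharynx", "pharynx_no_isthmus",
                                          "anterior_bulb", "terminal_bulb",
                                          "gonad"),
                                 grid = calibrated_grid(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "calibrated_grid"))
  cx <- grid$width_px / 2
  cy <- grid$height_px / 2

  withr::with_seed(seed, {
    if (kind == "gonad") {
      if (grid$width_px < 960) {
        rlang::abort("gonad fixture needs a grid at least 960 px wide (two fields of view)",
                     class = "ionpaint_shape_error")
      }
      w <- wobble(4)
      half_w <- 22 * w[1]
      x_in <- 0.08 * grid$width_px
      x_turn <- 0.88 * grid$width_px * w[2]
      y_top <- cy - 90 * w[3]
      y_bot <- cy + 90 * w[4]
      yc <- (y_top + y_bot) / 2
      rad <- (y_bot - y_top) / 2
      theta <- seq(-pi / 2, pi / 2, length.out = 24)
      path <- rbind(
        cbind(seq(x_in, x_turn, length.out = 40), y_top),
        cbind(x_turn + rad * cos(theta), yc + rad * sin(theta)),
        cbind(seq(x_turn, x_in, length.out = 40), y_bot)
      )
      mask <- band_mask(path, half_w, grid)
      meta <- list(kind = kind, half_width_px = half_w, seed = seed)
    } else {
      w <- wobble(6)
      ant <- list(cx = cx - 55 * w[1], cy = cy, a = 30 * w[2], b = 22 * w[3])
      term <- list(cx = cx + 45 * w[4], cy = cy, a = 35 * w[5], b = 28 * w[6])
      band_x0 <- ant$cx + ant$a - 10
      band_x1 <- term$cx - term$a + 10
      ant_m <- rasterize_shape(shape_ellipse(ant$cx, ant$cy, ant$a, ant$b), grid)
      term_m <- rasterize_shape(shape_ellipse(term$cx, term$cy, term$a, term$b), grid)
      isth_m <- rasterize_shape(
        shape_rectangle(band_x0, cy - 8, band_x1, cy + 8), grid
      )
      mask <- switch(kind,
        anterior_bulb = ant_m,
        terminal_bulb = term_m,
        pharynx = mask_union(mask_union(ant_m, term_m), isth_m),
        pharynx_no_isthmus = mask_exclude_cols(
          mask_union(ant_m, term_m), band_x0, band_x1
        )
      )
      meta <- list(kind = kind, anterior = ant, terminal = term,
                   isthmus_x = c(band_x0, band_x1), seed = seed)
    }
    attr(mask, "meta") <- meta
    mask
  })
}

mask_union <- function(a, b) {
  dplyr::distinct(dplyr::bind_rows(a, b))
}

mask_exclude_cols <- function(mask, x0, x1) {
  mask[mask$col + 0.5 < x0 | mask$col + 0.5 > x1, , drop = FALSE]
}

# pixels whose centre lies within half_w of the polyline `path` (n x 2 matrix)
band_mask <- function(path, half_w, grid) {
  xr <- range(path[, 1]) + c(-half_w - 1, half_w + 1)
  yr <- range(path[, 2]) + c(-half_w - 1, half_w + 1)
  cols <- (seq_len(grid$width_px) - 1L)
  rows <- (seq_len(grid$height_px) - 1L)
  cols <- cols[cols + 0.5 >= xr[1] & cols + 0.5 <= xr[2]]
  rows <- rows[rows + 0.5 >= yr[1] & rows + 0.5 <= yr[2]]
  px <- rep(cols, times = length(rows)) + 0.5
  py <- rep(rows, each = length(cols)) + 0.5
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
      d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2
    }
    dmin <- pmin(dmin, d2)
  }
  keep <- dmin <= half_w^2
  new_mask(col = (px - 0.5)[keep], row = (py - 0.5)[keep])
}
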