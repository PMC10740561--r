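# Virtual CR-39 read-out: renders planned hits as etch pits with beam-pointing
# spread and quantifies how uniformly a hit pattern fills its target.

#' Apply beam-pointing spread to a hit list
#'
#' Displaces every hit by a vector drawn uniformly on the disk of radius
#' `spot_um / 2`, modelling the focused beam spot as a hard-edged landing
#' spread: no displacement ever exceeds half the spot diameter. With
#' `spot_um = 0` the hit list is returned unchanged.
#'
#' @param hits A `hitlist` (see [plan_hits()]).
#' @param spot_um Beam spot diameter in um (>= 0).
#' @param seed Optional integer seed for an isolated draw.
#' @return A `hitlist` with jittered coordinates (same rows and order).
#' @export
apply_beam_jitter <- function(hits, spot_um, seed = NULL) {
  if (!is.finite(spot_um) || spot_um < 0) {
    rlang::abort("spot diameter must be >= 0 um", class = "ionpaint_beam_error")
  }
  if (spot_um == 0 || nrow(hits) == 0) return(hits)
  scale <- hit_scale(hits)
  with_optional_seed(seed, {
    n <- nrow(hits)
    r <- (spot_um / 2) * sqrt(stats::runif(n))
    theta <- stats::runif(n, 0, 2 * pi)
    hits$x_um <- hits$x_um + r * cos(theta)
    hits$y_um <- hits$y_um + r * sin(theta)
    hits$x <- hits$x_um / scale
    hits$y <- hits$y_um / scale
    hits
  })
}

#' Render hits as etch pits
#'
#' Produces a binary raster in which each hit is drawn as a disk of
#' `pit_um` diameter (pixel-centre inclusion), the optical appearance of
#' etched ion tracks on a CR-39 film. Overlapping pits merge (binary union).
#'
#' @param hits A `hitlist`.
#' @param grid A [calibrated_grid()] defining the output raster.
#' @param pit_um Visible etch-pit diameter in um (default 2, the smallest
#'   diameter reliably seen under an optical microscope).
#' @return A logical matrix `[height_px, width_px]` of class `pit_image`, with
#'   attributes `scale` (um/px) and `pit_um`.
#' @export
render_etch_pits <- function(hits, grid, pit_um = 2) {
  stopifnot(inherits(grid, "calibrated_grid"))
  if (!is.finite(pit_um) || pit_um < 0) {
    rlang::abort("pit diameter must be >= 0 um", class = "ionpaint_beam_error")
  }
  img <- matrix(FALSE, nrow = grid$height_px, ncol = grid$width_px)
  r_px <- (pit_um / 2) / grid$scale
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      hx <- hits$x_um[i] / grid$scale
      hy <- hits$y_um[i] / grid$scale
      cols <- max(0L, floor(hx - r_px - 1)):min(grid$width_px - 1L, ceiling(hx + r_px))
      rows <- max(0L, floor(hy - r_px - 1)):min(grid$height_px - 1L, ceiling(hy + r_px))
      if (cols[1] > cols[length(cols)] || rows[1] > rows[length(rows)]) next
      dx2 <- (cols + 0.5 - hx)^2
      dy2 <- (rows + 0.5 - hy)^2
      inside <- outer(dy2, dx2, "+") <= r_px^2
      img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] | inside
    }
  }
  structure(img, class = c("pit_image", "matrix"),
            scale = grid$scale, pit_um = pit_um)
}

#' @export
print.pit_image <- function(x, ...) {
  cat(sprintf("<pit_image> %d x %d px at %.6g um/px, %d foreground px\n",
              ncol(x), nrow(x), attr(x, "scale"), sum(x)))
  invisible(x)
}

#' Quadrat-count uniformity statistics
#'
#' Counts hits per quadrat cell and summarizes the spatial uniformity of the
#' pattern: mean count, sample variance, dispersion index `I = s^2 / mean`
#' (0 for perfectly even placement, ~1 for complete spatial randomness, > 1
#' for clumping), the chi-square statistic `sum((n_i - mean)^2) / mean` with
#' `m - 1` degrees of freedom, and the fraction of hits falling outside a
#' reference mask.
#'
#' Cells are either the stratification cells of [equal_count_partition()]
#' (pass `cells`) or a regular `q x q` grid of quadrats over the mask's
#' bounding box (pass `q`); quadrats that contain no mask pixel are dropped.
#'
#' @param hits A `hitlist`.
#' @param mask Reference mask tibble (the planned target).
#' @param grid A [calibrated_grid()].
#' @param cells Optional partition (mask tibble with a `cell` column).
#' @param q Number of quadrats per side when `cells` is not given.
#' @return A `uniformity_report` object; see [tidy.uniformity_report()] and
#'   [glance.uniformity_report()].
#' @export
quadrat_dispersion <- function(hits, mask, grid, cells = NULL, q = 10L) {
  assert_mask(mask, grid)
  pix_col <- pmin(pmax(floor(hits$x), 0), grid$width_px - 1L)
  pix_row <- pmin(pmax(floor(hits$y), 0), grid$height_px - 1L)
  hit_ids <- pix_row * grid$width_px + pix_col
  mask_ids <- pixel_id(mask, grid)
  outside <- if (nrow(hits)) mean(!(hit_ids %in% mask_ids)) else 0

  if (!is.null(cells)) {
    stopifnot("cell" %in% names(cells))
    if (length(unique(cells$cell)) < 2) {
      rlang::abort("need at least 2 quadrat cells", class = "ionpaint_partition_error")
    }
    cell_of <- stats::setNames(cells$cell, pixel_id(cells, grid))
    assigned <- cell_of[as.character(hit_ids)]
    counts <- tibble::tibble(cell = sort(unique(cells$cell))) |>
      dplyr::left_join(
        tibble::tibble(cell = as.integer(assigned[!is.na(assigned)])) |>
          dplyr::count(.data$cell),
        by = "cell"
      ) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  } else {
    if (q < 2) rlang::abort("need at least 2 quadrat cells",
                            class = "ionpaint_partition_error")
    xr <- range(mask$col); yr <- range(mask$row)
    wx <- (xr[2] + 1 - xr[1]) / q
    wy <- (yr[2] + 1 - yr[1]) / q
    qc <- function(col, row) {
      cx <- pmin(q - 1, pmax(0, floor((col - xr[1]) / wx)))
      cy <- pmin(q - 1, pmax(0, floor((row - yr[1]) / wy)))
      as.integer(cy * q + cx + 1)
    }
    occupied <- sort(unique(qc(mask$col, mask$row)))
    hq <- qc(hits$x, hits$y)
    counts <- tibble::tibble(cell = occupied) |>
      dplyr::left_join(
        tibble::tibble(cell = hq[hq %in% occupied]) |> dplyr::count(.data$cell),
        by = "cell"
      ) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }

  m <- nrow(counts)
  nbar <- mean(counts$n)
  if (nrow(hits) == 0 || nbar == 0) {
    s2 <- NA_real_; index <- NA_real_; chisq <- NA_real_; pval <- NA_real_
  } else {
    s2 <- stats::var(counts$n)
    index <- s2 / nbar
    chisq <- sum((counts$n - nbar)^2) / nbar
    pval <- stats::pchisq(chisq, df = m - 1, lower.tail = FALSE)
  }
  structure(
    list(counts = counts, n_cells = m, n_hits = nrow(hits), mean = nbar,
         var = s2, dispersion = index, chisq = chisq, df = m - 1,
         p_value = pval, outside_fraction = outside),
    class = "uniformity_report"
  )
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf(
    "<uniformity_report> %d hits in %d cells: mean %.3g, dispersion index %.3g, outside fraction %.3g\n",
    x$n_hits, x$n_cells, x$mean, x$dispersion, x$outside_fraction
  ))
  invisible(x)
}

#' Tidy a uniformity report
#'
#' @param x A `uniformity_report` from [quadrat_dispersion()].
#' @param ... Unused.
#' @return `tidy()`: the per-cell count tibble (`cell`, `n`). `glance()`: a
#'   one-row tibble with `n_cells`, `n_hits`, `mean`, `var`, `dispersion`,
#'   `chisq`, `df`, `p_value`, `outside_fraction`.
#' @export
tidy.uniformity_report <- function(x, ...) x$counts

#' @rdname tidy.uniformity_report
#' @export
glance.uniformity_report <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells, n_hits = x$n_hits, mean = x$mean, var = x$var,
    dispersion = x$dispersion, chisq = x$chisq, df = x$df,
    p_value = x$p_value, outside_fraction = x$outside_fraction
  )
}

#' Geometric bound on pit-region expansion
#'
#' A pit can extend beyond the target outline by at most half the beam spot
#' diameter (maximum landing displacement) plus half the pit diameter (pit
#' radius): `(spot_um + pit_um) / 2`. A dense irradiation of the mask boundary
#' approaches this bound; see [contour_expansion()].
#'
#' @param spot_um Beam spot diameter in um.
#' @param pit_um Etch-pit diameter in um.
#' @return The maximum expansion in um.
#' @examples
#' expansion_bound(5, 2) # 3.5 um
#' @export
expansion_bound <- function(spot_um, pit_um) {
  stopifnot(spot_um >= 0, pit_um >= 0)
  (spot_um + pit_um) / 2
}

#' Measured contour expansion of a pit image
#'
#' The maximum distance, in um, from the target-mask boundary to any pit
#' foreground pixel lying outside the mask -- the width by which the etched
#' area has expanded beyond the planned outline. Distances are measured from
#' pixel centres via a Euclidean distance transform of the mask, minus half a
#' pixel to approximate the distance to the mask region edge. Returns 0 when
#' no foreground lies outside the mask.
#'
#' @param pit A `pit_image` from [render_etch_pits()].
#' @param mask Target mask tibble (non-empty).
#' @param grid A [calibrated_grid()] matching the pit image.
#' @return Expansion in um.
#' @export
contour_expansion <- function(pit, mask, grid) {
  assert_mask(mask, grid)
  if (nrow(mask) == 0) {
    rlang::abort("target mask must be non-empty", class = "ionpaint_empty_mask_error")
  }
  stopifnot(nrow(pit) == grid$height_px, ncol(pit) == grid$width_px)
  mm <- mask_to_matrix(mask, grid)
  out_fg <- pit & !mm
  if (!any(out_fg)) return(0)
  d <- EBImage::distmap(1 - mm) # px distance of each outside pixel to mask
  max(0, (max(d[out_fg]) - 0.5) * grid$scale)
}

#' Realized dose map
#'
#' Bins hits into square blocks of `block_um` edge and converts each block's
#' count to an absorbed dose with [block_dose()]. Dose values are exact
#' integer multiples of the per-block dose quantum
#' `L * 0.1602 / block_um^2` -- the discreteness of natural-number ion counts
#' made visible. Total energy is conserved: `sum(dose) * block_um^2 =
#' n_hits * L * 0.1602`. The map extends beyond the grid if jittered hits
#' land outside it, so every hit is counted.
#'
#' @param hits A `hitlist`.
#' @param let LET in keV/um.
#' @param grid A [calibrated_grid()].
#' @param block_um Block edge in um (default 2).
#' @return A numeric matrix of Gy per block, class `dose_map`, with attributes
#'   `block_um`, `let`, and `origin_um` (physical coordinate of the `[1, 1]`
#'   block corner).
#' @export
realized_dose_map <- function(hits, let, grid, block_um = 2) {
  stopifnot(inherits(grid, "calibrated_grid"))
  if (!is.finite(block_um) || block_um <= 0) {
    rlang::abort("block edge must be > 0 um", class = "ionpaint_dose_error")
  }
  ext_x <- grid$width_px * grid$scale
  ext_y <- grid$height_px * grid$scale
  x0 <- min(0, if (nrow(hits)) floor(min(hits$x_um) / block_um) * block_um else 0)
  y0 <- min(0, if (nrow(hits)) floor(min(hits$y_um) / block_um) * block_um else 0)
  x1 <- max(ext_x, if (nrow(hits)) max(hits$x_um) else ext_x)
  y1 <- max(ext_y, if (nrow(hits)) max(hits$y_um) else ext_y)
  nbx <- ceiling((x1 - x0) / block_um)
  nby <- ceiling((y1 - y0) / block_um)
  counts <- matrix(0L, nrow = nby, ncol = nbx)
  if (nrow(hits)) {
    bx <- pmin(nbx - 1L, pmax(0L, floor((hits$x_um - x0) / block_um)))
    by <- pmin(nby - 1L, pmax(0L, floor((hits$y_um - y0) / block_um)))
    tab <- table(by * nbx + bx)
    idx <- as.integer(names(tab))
    counts[cbind(idx %/% nbx + 1L, idx %% nbx + 1L)] <- as.integer(tab)
  }
  dose <- block_dose(counts, let, block_um^2)
  structure(matrix(dose, nrow = nby), class = c("dose_map", "matrix"),
            block_um = block_um, let = let, origin_um = c(x0, y0))
}
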