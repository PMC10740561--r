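# shared grids and independent oracles

grid100 <- function() calibrated_grid(100, 100, 1)
grid_screen <- function() calibrated_grid() # 480 x 640 at 228.9/180 um/px

# independent oracle for disk pixel counts: per pixel-row closed form for the
# number of pixel centres inside the circle (no shared code with the
# rasterizer, which tests centres point-by-point)
disk_pixel_count_oracle <- function(cx, cy, r, width_px, height_px) {
  total <- 0L
  for (j in seq_len(height_px) - 1L) {
    dy <- j + 0.5 - cy
    if (abs(dy) > r) next
    w <- sqrt(r^2 - dy^2)
    lo <- ceiling(cx - w - 0.5)
    hi <- floor(cx + w - 0.5)
    lo <- max(lo, 0L)
    hi <- min(hi, width_px - 1L)
    if (hi >= lo) total <- total + (hi - lo + 1L)
  }
  total
}

# connected components of a mask (8-connectivity is not needed; the fixtures
# are 4-connected by construction) via an independent labelling routine
n_components <- function(mask, grid) {
  m <- matrix(FALSE, grid$height_px, grid$width_px)
  m[cbind(mask$row + 1L, mask$col + 1L)] <- TRUE
  max(EBImage::bwlabel(m))
}

# a mask covering a full rectangle of pixels (cols x0..x1-1, rows y0..y1-1)
rect_mask <- function(x0, y0, x1, y1, grid) {
  rasterize_shape(shape_rectangle(x0, y0, x1, y1), grid)
}

expect_same_hits <- function(a, b) {
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
}
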