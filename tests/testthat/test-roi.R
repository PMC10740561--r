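test_that("rectangle rasterization follows the pixel-centre rule", {
  g <- grid100()
  m <- rasterize_shape(shape_rectangle(0, 0, 10, 10), g)
  expect_equal(nrow(m), 100)
  expect_setequal(unique(m$col), 0:9)
  expect_setequal(unique(m$row), 0:9)
  # clipped to grid bounds
  m2 <- rasterize_shape(shape_rectangle(95, 95, 120, 120), g)
  expect_true(all(m2$col <= 99 & m2$row <= 99))
  expect_equal(nrow(m2), 25)
})

test_that("disk rasterization matches the per-row closed-form oracle", {
  g <- grid_screen()
  m <- rasterize_shape(shape_ellipse(g$width_px / 2, g$height_px / 2, 90), g)
  oracle <- disk_pixel_count_oracle(g$width_px / 2, g$height_px / 2, 90,
                                    g$width_px, g$height_px)
  expect_equal(nrow(m), oracle)
  expect_equal(oracle, 25448) # frozen from the oracle
  expect_lt(abs(nrow(m) - pi * 90^2) / (pi * 90^2), 0.01)
})

test_that("degenerate shapes raise an empty-mask error", {
  g <- grid100()
  tri <- shape_polygon(rbind(c(5, 5), c(5, 5), c(5, 5)))
  expect_error(rasterize_shape(tri, g), class = "ionpaint_empty_mask_error")
  expect_error(rasterize_shape(shape_rectangle(3, 3, 3, 9), g),
               class = "ionpaint_empty_mask_error")
  expect_error(shape_ellipse(5, 5, 0), class = "ionpaint_shape_error")
})

test_that("rasterization is deterministic and idempotent", {
  g <- grid100()
  sp <- shape_polygon(rbind(c(10, 10), c(80, 20), c(60, 90), c(15, 70)))
  expect_identical(rasterize_shape(sp, g), rasterize_shape(sp, g))
  spl <- shape_cardinal_spline(rbind(c(50, 20), c(80, 50), c(50, 80), c(20, 50)))
  expect_identical(rasterize_shape(spl, g), rasterize_shape(spl, g))
})

test_that("a closed cardinal spline through diamond points encloses a round blob", {
  g <- grid100()
  m <- rasterize_shape(
    shape_cardinal_spline(rbind(c(50, 20), c(80, 50), c(50, 80), c(20, 50))), g
  )
  # between the control diamond (area 1800) and its bounding square (3600)
  expect_gt(nrow(m), 1800)
  expect_lt(nrow(m), 3600)
  # at tension 1 the spline degenerates to the control polygon
  m1 <- rasterize_shape(
    shape_cardinal_spline(rbind(c(50, 20), c(80, 50), c(50, 80), c(20, 50)),
                          tension = 1), g
  )
  mp <- rasterize_shape(
    shape_polygon(rbind(c(50, 20), c(80, 50), c(50, 80), c(20, 50))), g
  )
  expect_equal(dplyr::arrange(m1, row, col), dplyr::arrange(mp, row, col))
})

test_that("binarize_image is threshold-inclusive and range-checked", {
  img <- matrix(10, 4, 4)
  expect_equal(nrow(binarize_image(img, 10)), 16)
  expect_equal(nrow(binarize_image(matrix(9, 4, 4), 10)), 0)
  half <- cbind(matrix(0, 4, 2), matrix(255, 4, 2))
  m <- binarize_image(half, 128)
  expect_setequal(unique(m$col), 2:3)
  expect_equal(nrow(m), 8)
  expect_error(binarize_image(img, 300), class = "ionpaint_threshold_error")
  expect_error(binarize_image(img, -1), class = "ionpaint_threshold_error")
})

test_that("brightness partition is an exact partition with per-band doses", {
  g <- grid100()
  img <- make_gradient_image(g)
  rg <- partition_by_brightness(img, c(64, 128, 192), c(0, 0.5, 1.5, 2.5))
  expect_equal(nrow(rg), 4)
  expect_equal(rg$dose, c(0, 0.5, 1.5, 2.5))
  ids <- unlist(lapply(rg$mask, function(m) m$row * 100 + m$col))
  expect_equal(anyDuplicated(ids), 0L) # pairwise disjoint
  expect_equal(length(ids), 100 * 100) # full coverage
  # bands of a monotone horizontal ramp are vertical stripes
  cols3 <- range(rg$mask[[3]]$col)
  expect_true(all(rg$mask[[2]]$col < cols3[1]))
  expect_true(all(rg$mask[[4]]$col > cols3[2]))
})

test_that("brightness partition properties hold for random thresholds", {
  g <- calibrated_grid(40, 40, 1)
  withr::with_seed(11, {
    for (rep in 1:5) {
      img <- matrix(sample(0:255, 1600, replace = TRUE), 40, 40)
      attr(img, "bits") <- 8L
      th <- sort(sample(1:254, 3))
      rg <- partition_by_brightness(img, th, runif(4, 0, 3))
      ids <- unlist(lapply(rg$mask, function(m) m$row * 40 + m$col))
      expect_equal(anyDuplicated(ids), 0L)
      expect_equal(length(ids), 1600)
    }
  })
  expect_error(partition_by_brightness(make_gradient_image(g), c(100, 100),
                                       c(1, 2, 3)),
               class = "ionpaint_threshold_error")
  # single threshold reduces to binarize_image
  img <- make_gradient_image(g)
  rg <- partition_by_brightness(img, 128, c(0, 1))
  expect_equal(dplyr::arrange(rg$mask[[2]], row, col),
               dplyr::arrange(binarize_image(img, 128), row, col))
})

test_that("mask_area is the calibrated pixel area times the count, and additive", {
  g1 <- grid100()
  expect_equal(mask_area(rect_mask(0, 0, 10, 10, g1), g1), 100)
  gs <- grid_screen()
  one <- tibble::tibble(col = 0L, row = 0L)
  expect_equal(mask_area(one, gs), (228.9 / 180)^2)
  expect_equal(mask_area(tibble::tibble(col = integer(), row = integer()), g1), 0)
  a <- rect_mask(0, 0, 10, 10, g1)
  b <- rect_mask(20, 20, 33, 27, g1)
  expect_equal(mask_area(dplyr::bind_rows(a, b), g1),
               mask_area(a, g1) + mask_area(b, g1))
})
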