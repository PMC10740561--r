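test_that("equal-count partition balances cell sizes, larger chunks first", {
  g <- grid100()
  sq <- rect_mask(0, 0, 10, 10, g)
  p4 <- equal_count_partition(sq, 4)
  expect_equal(unname(as.vector(table(p4$cell))), rep(25L, 4))

  m103 <- rect_mask(0, 0, 103, 1, calibrated_grid(110, 5, 1)) # 103 pixels
  sizes <- as.vector(table(equal_count_partition(m103, 4)$cell))
  expect_equal(unname(sizes), c(26L, 26L, 26L, 25L))

  p1 <- equal_count_partition(sq, 1)
  expect_equal(unique(p1$cell), 1L)
  expect_equal(nrow(p1), 100)

  expect_error(equal_count_partition(sq, 101), class = "ionpaint_partition_error")
  expect_error(equal_count_partition(sq, 0), class = "ionpaint_partition_error")
})

test_that("partition traversal is serpentine and cells are contiguous in it", {
  g <- grid100()
  sq <- rect_mask(0, 0, 6, 4, g)
  p <- equal_count_partition(sq, 1)
  expect_equal(p$row, rep(0:3, each = 6))
  expect_equal(p$col[1:6], 0:5)   # even rows left to right
  expect_equal(p$col[7:12], 5:0)  # odd rows right to left
  p3 <- equal_count_partition(sq, 3)
  expect_true(all(diff(p3$cell) >= 0)) # cells are contiguous chunks
})

test_that("random-coordinate sampling places exactly n hits inside the mask", {
  g <- grid100()
  m <- rasterize_shape(shape_ellipse(50, 50, 30, 20), g)
  h <- sample_random_coordinate(m, 777, g, seed = 1)
  expect_equal(nrow(h), 777)
  ids <- floor(h$y) * 100 + floor(h$x)
  expect_true(all(ids %in% (m$row * 100 + m$col)))
  expect_equal(nrow(sample_random_coordinate(m, 0, g)), 0)
  empty <- tibble::tibble(col = integer(), row = integer())
  expect_error(sample_random_coordinate(empty, 3, g),
               class = "ionpaint_empty_mask_error")
})

test_that("pixel-probability sampling is Bernoulli per pixel", {
  g <- grid100()
  m <- rect_mask(0, 0, 100, 100, g)
  # p = 1: every pixel hit exactly once
  h <- sample_pixel_probability(m, nrow(m), g, seed = 2)
  expect_equal(nrow(h), nrow(m))
  expect_equal(anyDuplicated(floor(h$y) * 100 + floor(h$x)), 0L)
  expect_equal(nrow(sample_pixel_probability(m, 0, g)), 0)
  # binomial mean: average total over 200 seeds close to n
  n <- 500; p <- n / nrow(m)
  totals <- vapply(1:200, function(s) nrow(sample_pixel_probability(m, n, g, seed = s)),
                   numeric(1))
  se <- sqrt(n * (1 - p) / 200)
  expect_lt(abs(mean(totals) - n), 3 * se)
  # total varies between seeds (not renormalized to n)
  expect_gt(stats::var(totals), 0)
})

test_that("even-random sampling puts exactly one hit in every stratification cell", {
  g <- grid100()
  m <- rect_mask(0, 0, 100, 100, g)
  h <- sample_even_random(m, 500, g, seed = 3)
  expect_equal(nrow(h), 500)
  expect_equal(sort(unique(h$cell)), 1:500)
  expect_equal(unname(as.vector(table(h$cell))), rep(1L, 500)) # zero count variance
  h1 <- sample_even_random(m, 1, g, seed = 3)
  expect_equal(nrow(h1), 1)
  expect_identical(sample_even_random(m, 50, g, seed = 9),
                   sample_even_random(m, 50, g, seed = 9))
})

test_that("plan_hits delivers the dosimetric ion count per region", {
  g <- calibrated_grid(200, 10, 1)
  ra <- region("a", rect_mask(0, 0, 100, 10, g), dose = 1) # 1000 px
  rb <- region("b", rect_mask(100, 0, 200, 10, g), dose = 2) # 1000 px
  beam <- beam_parameters(let = 80)
  for (meth in c("even_random", "random_coordinate")) {
    h <- plan_hits(dplyr::bind_rows(ra, rb), g, beam, method = meth, seed = 5)
    counts <- table(h$region)
    expect_equal(unname(counts[["a"]]), 78)  # round(1 * 1000 / 12.816)
    expect_equal(unname(counts[["b"]]), 156) # round(2 * 1000 / 12.816)
  }
})

test_that("plan_hits rejects overlapping regions and handles empty input", {
  g <- grid100()
  ra <- region("a", rect_mask(0, 0, 50, 50, g), dose = 1)
  rb <- region("b", rect_mask(40, 40, 80, 80, g), dose = 1)
  expect_error(plan_hits(dplyr::bind_rows(ra, rb), g, beam_parameters()),
               class = "ionpaint_overlap_error")
  h0 <- plan_hits(ra[0, ], g, beam_parameters(), seed = 1)
  expect_equal(nrow(h0), 0)
  # dose 0 regions receive no ions
  rz <- region("z", rect_mask(60, 60, 90, 90, g), dose = 0)
  h <- plan_hits(dplyr::bind_rows(ra, rz), g, beam_parameters(let = 80), seed = 1)
  expect_false("z" %in% h$region)
})

test_that("plans are deterministic and independent of region order", {
  g <- grid100()
  ra <- region("a", rect_mask(0, 0, 40, 40, g), dose = 1.5)
  rb <- region("b", rasterize_shape(shape_ellipse(70, 70, 20, 15), g), dose = 0.7)
  beam <- beam_parameters(let = 80)
  h1 <- plan_hits(dplyr::bind_rows(ra, rb), g, beam, seed = 42)
  h2 <- plan_hits(dplyr::bind_rows(ra, rb), g, beam, seed = 42)
  expect_identical(tibble::as_tibble(h1), tibble::as_tibble(h2))
  h3 <- plan_hits(dplyr::bind_rows(rb, ra), g, beam, seed = 42)
  key <- function(h) dplyr::arrange(tibble::as_tibble(h)[, -1], region, x, y)
  expect_equal(key(h1), key(h3))
  # different seed, different coordinates
  h4 <- plan_hits(dplyr::bind_rows(ra, rb), g, beam, seed = 43)
  expect_false(identical(h1$x, h4$x))
})

test_that("base ions fill every pixel once per pass when P exceeds the pixel count", {
  g <- calibrated_grid(10, 10, 1)
  m <- rect_mask(0, 0, 2, 2, g) # 4 px, 4 um^2
  beam <- beam_parameters(let = 80)
  # dose for exactly 9 ions: base 2 per pixel + 1 remainder
  d9 <- block_dose(9, 80, 4)
  r <- region("hot", m, d9)
  h <- plan_hits(r, g, beam, seed = 8)
  expect_equal(nrow(h), 9)
  ids <- floor(h$y) * 10 + floor(h$x)
  expect_true(all(ids %in% (m$row * 10 + m$col)))
  counts <- table(ids)
  expect_true(all(counts >= 2) && sum(counts) == 9)
})

test_that("all methods coincide when the remainder is zero", {
  g <- calibrated_grid(10, 10, 1)
  m <- rect_mask(0, 0, 5, 2, g) # 10 px
  d <- block_dose(20, 80, 10) # exactly 2 ions per pixel, remainder 0
  r <- region("flat", m, d)
  hs <- lapply(c("even_random", "random_coordinate", "pixel_probability"),
               function(meth) plan_hits(r, g, beam_parameters(let = 80),
                                        method = meth, seed = 12))
  expect_identical(tibble::as_tibble(hs[[1]]), tibble::as_tibble(hs[[2]]))
  expect_identical(tibble::as_tibble(hs[[1]]), tibble::as_tibble(hs[[3]]))
  expect_equal(nrow(hs[[1]]), 20)
})
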