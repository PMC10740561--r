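# Placement of discrete ion hits inside region masks.
#
# The planner distributes P = ion_count(D, S, L) ions over a mask: a whole
# number of "base" ions per pixel plus a remainder R < |mask| that must be
# spread as uniformly as possible. Three remainder methods are provided --
# random_coordinate, pixel_probability and even_random (stratified sampling,
# the production method).

# serpentine (boustrophedon) traversal: row-major, alternating column
# direction, starting left-to-right on the first (lowest) row present
order_serpentine <- function(mask) {
  key <- ifelse(mask$row %% 2L == 0L, mask$col, -mask$col)
  mask[order(mask$row, key), , drop = FALSE]
}

#' Partition a mask into equal-count cells
#'
#' Splits a mask into `r` cells of near-equal pixel count -- the stratification
#' grid of the even random method, generalized to arbitrary mask shapes. The
#' mask pixels are ordered by a row-major serpentine (boustrophedon) traversal
#' and cut into `r` contiguous chunks whose sizes differ by at most one pixel,
#' larger chunks first.
#'
#' @param mask Mask tibble (`col`, `row`).
#' @param r Number of cells, `1 <= r <= nrow(mask)`.
#' @return The serpentine-ordered mask tibble with an integer `cell` column
#'   (1-based cell index).
#' @examples
#' g <- calibrated_grid(10, 10, 1)
#' m <- rasterize_shape(shape_rectangle(0, 0, 10, 10), g)
#' table(equal_count_partition(m, 4)$cell) # 25 pixels per cell
#' @export
equal_count_partition <- function(mask, r) {
  assert_mask(mask)
  n <- nrow(mask)
  if (!is.finite(r) || r < 1 || r != floor(r) || r > n) {
    rlang::abort(sprintf("cell count r must be an integer in [1, %d]", n),
                 class = "ionpaint_partition_error")
  }
  ordered <- order_serpentine(mask)
  base <- n %/% r
  extra <- n %% r
  sizes <- rep(base, r) + c(rep(1L, extra), rep(0L, r - extra))
  ordered$cell <- rep.int(seq_len(r), sizes)
  ordered
}

# uniform continuous offset inside each pixel
jitter_within_pixel <- function(px) {
  tibble::tibble(x = px$col + stats::runif(nrow(px)),
                 y = px$row + stats::runif(nrow(px)))
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

new_hitlist <- function(df, scale) {
  df$hit <- seq_len(nrow(df))
  df <- df[, intersect(c("hit", "region", "cell", "x", "y"), names(df)), drop = FALSE]
  df$x_um <- df$x * scale
  df$y_um <- df$y * scale
  out <- tibble::as_tibble(df)
  attr(out, "scale") <- scale
  class(out) <- c("hitlist", class(out))
  out
}

hit_scale <- function(hits) {
  s <- attr(hits, "scale")
  if (is.null(s)) {
    if (nrow(hits)) s <- hits$x_um[1] / hits$x[1] else s <- 1
  }
  s
}

#' @export
print.hitlist <- function(x, ...) {
  cat(sprintf("<hitlist> %d hits, %d region(s), scale %.6g um/px\n",
              nrow(x), length(unique(x$region)), hit_scale(x)))
  NextMethod()
}

#' Hit placement methods
#'
#' Place `n` ion hits inside a mask with one of the three remainder-placement
#' methods:
#' \describe{
#'   \item{`sample_random_coordinate()`}{each hit at an independently uniform
#'     position in the mask (a uniformly chosen pixel, then a uniform offset
#'     within it). Exactly `n` hits; the pattern is completely spatially
#'     random and therefore locally clumpy (quadrat dispersion index ~ 1).}
#'   \item{`sample_pixel_probability()`}{every mask pixel independently
#'     receives one hit with probability `p = n / |mask|`. The total hit count
#'     is Binomial(|mask|, p), not exactly `n`.}
#'   \item{`sample_even_random()`}{stratified sampling: the mask is first
#'     split into `n` equal-count cells ([equal_count_partition()]) and one
#'     hit is placed uniformly inside each cell. Exactly `n` hits, zero
#'     count variance at the stratification scale -- uniform yet random.}
#' }
#'
#' @param mask Mask tibble (`col`, `row`).
#' @param n Number of hits (remainder ions) to place.
#' @param grid A [calibrated_grid()] providing the um/px scale.
#' @param seed Optional integer seed; when given the draw is made in an
#'   isolated RNG state so the caller's stream is untouched.
#' @return A `hitlist` tibble: `hit`, `region`, (`cell`,) `x`, `y` (continuous
#'   pixel coordinates), `x_um`, `y_um`.
#' @name hit_sampling
#' @examples
#' g <- calibrated_grid(100, 100, 1)
#' m <- rasterize_shape(shape_rectangle(0, 0, 100, 100), g)
#' h <- sample_even_random(m, 500, g, seed = 1)
#' nrow(h)
NULL

#' @rdname hit_sampling
#' @export
sample_random_coordinate <- function(mask, n, grid, seed = NULL) {
  assert_mask(mask, grid)
  if (n == 0) return(new_hitlist(empty_hits(), grid$scale))
  if (nrow(mask) == 0) {
    rlang::abort("cannot place hits in an empty mask", class = "ionpaint_empty_mask_error")
  }
  with_optional_seed(seed, {
    idx <- sample.int(nrow(mask), n, replace = TRUE)
    xy <- jitter_within_pixel(mask[idx, , drop = FALSE])
    new_hitlist(data.frame(region = "mask", x = xy$x, y = xy$y), grid$scale)
  })
}

#' @rdname hit_sampling
#' @export
sample_pixel_probability <- function(mask, n, grid, seed = NULL) {
  assert_mask(mask, grid)
  if (n == 0) return(new_hitlist(empty_hits(), grid$scale))
  if (nrow(mask) == 0) {
    rlang::abort("cannot place hits in an empty mask", class = "ionpaint_empty_mask_error")
  }
  if (n > nrow(mask)) {
    rlang::abort("pixel-probability method requires n <= |mask|",
                 class = "ionpaint_partition_error")
  }
  p <- n / nrow(mask)
  with_optional_seed(seed, {
    ordered <- order_serpentine(mask)
    hitp <- stats::runif(nrow(ordered)) < p
    xy <- jitter_within_pixel(ordered[hitp, , drop = FALSE])
    new_hitlist(data.frame(region = rep("mask", sum(hitp)), x = xy$x, y = xy$y),
                grid$scale)
  })
}

#' @rdname hit_sampling
#' @export
sample_even_random <- function(mask, n, grid, seed = NULL) {
  assert_mask(mask, grid)
  if (n == 0) return(new_hitlist(empty_hits(), grid$scale))
  parts <- equal_count_partition(mask, n)
  with_optional_seed(seed, {
    picked <- parts |>
      dplyr::group_by(.data$cell) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$cell)
    xy <- jitter_within_pixel(picked)
    new_hitlist(data.frame(region = "mask", cell = picked$cell,
                           x = xy$x, y = xy$y), grid$scale)
  })
}

empty_hits <- function() {
  data.frame(region = character(), cell = integer(),
             x = numeric(), y = numeric())
}

# deterministic per-region RNG substream seed: a 31-bit polynomial hash of the
# region label folded into the master seed, so adding or reordering regions
# never perturbs another region's hits
region_seed <- function(master, label) {
  h <- 0
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Plan ion hits for a multi-region irradiation
#'
#' The core planning step: for each region, converts the prescribed dose to an
#' ion count `P = ion_count(D, S, L)`, splits it into base ions per pixel plus
#' a remainder ([decompose_per_pixel()]), places the base ions once per pixel
#' per pass (uniform sub-pixel offset) and spreads the remainder with the
#' chosen method. Regions are processed with independent RNG substreams
#' derived from `(seed, label)`, so an identical plan and seed reproduces the
#' hit list bit-exactly regardless of region order.
#'
#' @param regions Regions tibble ([region()] rows); masks must be pairwise
#'   disjoint.
#' @param grid A [calibrated_grid()].
#' @param beam A [beam_parameters()].
#' @param method One of `"even_random"` (default, the production method),
#'   `"random_coordinate"`, `"pixel_probability"`.
#' @param seed Integer master seed.
#' @return A `hitlist` tibble ordered by region, then base passes in
#'   serpentine pixel order, then remainder hits in cell/serpentine order.
#' @examples
#' g <- calibrated_grid(100, 100, 1)
#' rg <- region("target", rasterize_shape(shape_ellipse(50, 50, 30), g), dose = 1)
#' plan_hits(rg, g, beam_parameters(let = 80), seed = 1)
#' @export
plan_hits <- function(regions, grid, beam,
                      method = c("even_random", "random_coordinate",
                                 "pixel_probability"),
                      seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "calibrated_grid"), inherits(beam, "beam_parameters"))
  if (nrow(regions) == 0) return(new_hitlist(empty_hits(), grid$scale))
  if (anyDuplicated(regions$label)) {
    rlang::abort("region labels must be unique", class = "ionpaint_overlap_error")
  }
  all_ids <- unlist(purrr::map(regions$mask, pixel_id, grid = grid))
  if (anyDuplicated(all_ids)) {
    rlang::abort("regions overlap: a pixel may carry only one dose",
                 class = "ionpaint_overlap_error")
  }

  per_region <- purrr::map(seq_len(nrow(regions)), function(i) {
    mask <- regions$mask[[i]]
    assert_mask(mask, grid)
    label <- regions$label[i]
    dose <- regions$dose[i]
    if (dose == 0 || nrow(mask) == 0) return(empty_hits())
    p <- ion_count(dose, mask_area(mask, grid), beam$let)
    if (p == 0) return(empty_hits())
    split <- decompose_per_pixel(p, nrow(mask))
    withr::with_seed(region_seed(seed, label), {
      ordered <- order_serpentine(mask)
      base_hits <- if (split$base > 0) {
        purrr::map_dfr(seq_len(split$base), function(pass) {
          xy <- jitter_within_pixel(ordered)
          data.frame(region = label, cell = NA_integer_, x = xy$x, y = xy$y)
        })
      } else empty_hits()
      rem_hits <- if (split$remainder > 0) {
        r <- split$remainder
        h <- switch(method,
          even_random = sample_even_random(mask, r, grid),
          random_coordinate = sample_random_coordinate(mask, r, grid),
          pixel_probability = sample_pixel_probability(mask, r, grid)
        )
        data.frame(region = rep(label, nrow(h)),
                   cell = if ("cell" %in% names(h)) h$cell else
                     rep(NA_integer_, nrow(h)),
                   x = h$x, y = h$y)
      } else empty_hits()
      dplyr::bind_rows(base_hits, rem_hits)
    })
  })
  new_hitlist(dplyr::bind_rows(per_region), grid$scale)
}
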