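# Plan-file and scan-list formats, raster I/O, scanner voltage calibration.
#
# A plan is a single YAML document replacing the interactive region-selection
# workflow: grid calibration, beam parameters, regions (shapes, mask files or
# a brightness partition) with per-region doses, placement method and seed.

#' Scanner voltage calibration
#'
#' Per-axis affine map from physical um coordinates to beam-scanner voltages:
#' `v = gain * coordinate_um + offset`. Exported scan lists gain optional
#' voltage columns when a calibration is supplied; coordinates that map
#' outside `[vmin, vmax]` are rejected.
#'
#' @param gain_x,gain_y Gains in V/um (nonzero).
#' @param offset_x,offset_y Offsets in V.
#' @param vmin,vmax Voltage limits in V.
#' @return A `scanner_calibration` object.
#' @examples
#' scanner_calibration(gain_x = 0.01, offset_x = -1) # 228.9 um -> 1.289 V
#' @export
scanner_calibration <- function(gain_x = 1, offset_x = 0,
                                gain_y = gain_x, offset_y = offset_x,
                                vmin = -Inf, vmax = Inf) {
  if (gain_x == 0 || gain_y == 0) {
    rlang::abort("scanner gain must be nonzero", class = "ionpaint_calibration_error")
  }
  structure(list(gain_x = gain_x, offset_x = offset_x,
                 gain_y = gain_y, offset_y = offset_y,
                 vmin = vmin, vmax = vmax),
            class = "scanner_calibration")
}

#' Export a hit list as a scanner-ready scan list
#'
#' Writes the hit list as CSV with columns `hit_index`, `region_label`,
#' `x_px`, `y_px`, `x_um`, `y_um` and, when a [scanner_calibration()] is
#' given, `vx_volt`, `vy_volt`. Row order is the hit order (the scan order);
#' coordinates are printed with fixed 4-decimal precision.
#'
#' @param hits A `hitlist`.
#' @param path Output file path.
#' @param calibration Optional [scanner_calibration()].
#' @return `path`, invisibly.
#' @export
export_scan_list <- function(hits, path, calibration = NULL) {
  if (nrow(hits) && !all(is.finite(hits$x_um) & is.finite(hits$y_um))) {
    rlang::abort("hit coordinates must be finite", class = "ionpaint_scanlist_error")
  }
  df <- data.frame(
    hit_index = hits$hit,
    region_label = hits$region,
    x_px = sprintf("%.4f", hits$x),
    y_px = sprintf("%.4f", hits$y),
    x_um = sprintf("%.4f", hits$x_um),
    y_um = sprintf("%.4f", hits$y_um)
  )
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "scanner_calibration"))
    vx <- calibration$gain_x * hits$x_um + calibration$offset_x
    vy <- calibration$gain_y * hits$y_um + calibration$offset_y
    bad <- which(vx < calibration$vmin | vx > calibration$vmax |
                   vy < calibration$vmin | vy > calibration$vmax)
    if (length(bad)) {
      rlang::abort(
        sprintf("hit %d maps outside the scanner voltage limits [%g, %g] V",
                hits$hit[bad[1]], calibration$vmin, calibration$vmax),
        class = "ionpaint_voltage_error"
      )
    }
    df$vx_volt <- sprintf("%.4f", vx)
    df$vy_volt <- sprintf("%.4f", vy)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scan list back into a hit list
#'
#' @param path CSV file written by [export_scan_list()].
#' @param scale um/px scale to attach (recovered from the coordinate columns
#'   when omitted).
#' @return A `hitlist` tibble.
#' @export
read_scan_list <- function(path, scale = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hit_index", "region_label", "x_px", "y_px", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    rlang::abort("not a scan list: missing required columns",
                 class = "ionpaint_scanlist_error")
  }
  scale <- scale %||% (if (nrow(df)) stats::median(df$x_um / df$x_px, na.rm = TRUE) else 1)
  out <- tibble::tibble(hit = df$hit_index, region = df$region_label,
                        x = df$x_px, y = df$y_px,
                        x_um = df$x_um, y_um = df$y_um)
  attr(out, "scale") <- scale
  class(out) <- c("hitlist", class(out))
  out
}

#' Read and write masks and grayscale images as PNG/TIFF
#'
#' Masks are written as single-channel rasters with foreground = nonzero;
#' grayscale images as normalized intensities. The file format follows the
#' extension (`.png` or `.tif`/`.tiff`).
#'
#' @param mask Mask tibble.
#' @param grid A [calibrated_grid()].
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth for images (8 or 16).
#' @return `write_*`: `path` invisibly. `read_mask_raster()`: a mask tibble.
#'   `read_image_raster()`: an intensity matrix with a `bits` attribute.
#' @name raster_io
NULL

raster_writer <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG,
    tif = ,
    tiff = function(image, target) tiff::writeTIFF(image, target),
    rlang::abort(sprintf("unsupported raster format '.%s'", ext),
                 class = "ionpaint_io_error")
  )
}

raster_reader <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG,
    tif = ,
    tiff = function(p) {
      img <- tiff::readTIFF(p)
      img
    },
    rlang::abort(sprintf("unsupported raster format '.%s'", ext),
                 class = "ionpaint_io_error")
  )
}

#' @rdname raster_io
#' @export
write_mask_raster <- function(mask, grid, path) {
  assert_mask(mask, grid)
  raster_writer(path)(mask_to_matrix(mask, grid) * 1, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask_raster <- function(path) {
  img <- raster_reader(path)(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix_to_mask(img > 0)
}

#' @rdname raster_io
#' @param image Intensity matrix (values in `[0, 2^bits - 1]`).
#' @export
write_image_raster <- function(image, path, bits = 8L) {
  stopifnot(is.matrix(image))
  raster_writer(path)(image / (2^bits - 1), path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_image_raster <- function(path, bits = 8L) {
  img <- raster_reader(path)(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  out <- round(img * (2^bits - 1))
  attr(out, "bits") <- as.integer(bits)
  out
}

# --- plan files --------------------------------------------------------------

plan_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ionpaint_plan_error"))
}

shape_from_config <- function(cfg) {
  kind <- cfg$kind %||% plan_abort("shape needs a `kind`", "ionpaint_schema_error")
  pts <- function() do.call(rbind, lapply(cfg$points, unlist))
  switch(kind,
    rectangle = shape_rectangle(cfg$x0, cfg$y0, cfg$x1, cfg$y1),
    ellipse = shape_ellipse(cfg$cx, cfg$cy, cfg$a, cfg$b %||% cfg$a),
    polygon = shape_polygon(pts()),
    cardinal_spline = shape_cardinal_spline(pts(), cfg$tension %||% 0),
    plan_abort(sprintf("unknown shape kind '%s'", kind), "ionpaint_schema_error")
  )
}

#' Load and validate an irradiation plan
#'
#' Reads a YAML plan document and returns a fully validated plan: calibrated
#' grid, beam parameters, rasterized regions with doses, placement method and
#' seed. Regions may be given as shapes, as mask raster files (paths resolved
#' relative to the plan file), or as a brightness partition of a grayscale
#' image. Overlapping regions are rejected.
#'
#' @param path Path to a YAML plan file.
#' @return A list of class `irradiation_plan`: `grid`, `beam`, `regions`,
#'   `method`, `seed`, `config` (the raw document).
#' @export
load_plan <- function(path) {
  if (!file.exists(path)) {
    plan_abort(sprintf("plan file '%s' not found", path), "ionpaint_missing_file_error")
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("grid", "beam", "regions")) {
    if (is.null(cfg[[field]])) {
      plan_abort(sprintf("plan is missing required field `%s`", field),
                 "ionpaint_schema_error")
    }
  }
  g <- cfg$grid
  if (is.null(g$width_px) || is.null(g$height_px) || is.null(g$scale_um_per_px)) {
    plan_abort("grid needs width_px, height_px and scale_um_per_px",
               "ionpaint_schema_error")
  }
  grid <- calibrated_grid(g$width_px, g$height_px, g$scale_um_per_px)
  b <- cfg$beam
  if (is.null(b$let_kev_um)) {
    plan_abort("beam needs let_kev_um", "ionpaint_schema_error")
  }
  beam <- beam_parameters(b$ion %||% "ion", b$let_kev_um, b$spot_um %||% 0)

  base_dir <- dirname(normalizePath(path))
  regions <- purrr::map_dfr(cfg$regions, function(rc) {
    label <- rc$label %||% plan_abort("every region needs a `label`",
                                      "ionpaint_schema_error")
    if (is.null(rc$dose_gy) && is.null(rc$doses_gy)) {
      plan_abort(sprintf("region '%s' needs dose_gy", label), "ionpaint_schema_error")
    }
    if (!is.null(rc$shape)) {
      region(label, rasterize_shape(shape_from_config(rc$shape), grid), rc$dose_gy)
    } else if (!is.null(rc$mask_file)) {
      mf <- file.path(base_dir, rc$mask_file)
      if (!file.exists(mf)) {
        plan_abort(sprintf("mask file '%s' not found", rc$mask_file),
                   "ionpaint_missing_file_error")
      }
      region(label, read_mask_raster(mf), rc$dose_gy)
    } else if (!is.null(rc$image_file)) {
      imf <- file.path(base_dir, rc$image_file)
      if (!file.exists(imf)) {
        plan_abort(sprintf("image file '%s' not found", rc$image_file),
                   "ionpaint_missing_file_error")
      }
      img <- read_image_raster(imf, rc$bits %||% 8L)
      if (!is.null(rc$thresholds)) {
        pb <- partition_by_brightness(img, unlist(rc$thresholds),
                                      unlist(rc$doses_gy),
                                      labels = paste0(label, "_", seq_along(rc$doses_gy)))
        pb
      } else {
        region(label, binarize_image(img, rc$threshold %||% 1), rc$dose_gy)
      }
    } else {
      plan_abort(sprintf("region '%s' needs a shape, mask_file or image_file", label),
                 "ionpaint_schema_error")
    }
  })

  ids <- unlist(purrr::map(regions$mask, pixel_id, grid = grid))
  if (anyDuplicated(ids)) {
    plan_abort("plan regions overlap", "ionpaint_overlap_error")
  }
  method <- cfg$method %||% "even_random"
  if (!method %in% c("even_random", "random_coordinate", "pixel_probability")) {
    plan_abort(sprintf("unknown method '%s'", method), "ionpaint_schema_error")
  }
  structure(
    list(grid = grid, beam = beam, regions = regions, method = method,
         seed = as.integer(cfg$seed %||% 1L), config = cfg),
    class = "irradiation_plan"
  )
}

#' @export
print.irradiation_plan <- function(x, ...) {
  cat(sprintf("<irradiation_plan> %d region(s), method %s, seed %d\n",
              nrow(x$regions), x$method, x$seed))
  print(x$grid)
  print(x$beam)
  invisible(x)
}

#' Execute a plan end to end
#'
#' Convenience wrapper: [plan_hits()] on a loaded plan, with the plan's own
#' method and seed unless overridden.
#'
#' @param plan An `irradiation_plan` from [load_plan()].
#' @param method,seed Optional overrides.
#' @return A `hitlist`.
#' @export
run_plan <- function(plan, method = NULL, seed = NULL) {
  stopifnot(inherits(plan, "irradiation_plan"))
  plan_hits(plan$regions, plan$grid, plan$beam,
            method = method %||% plan$method, seed = seed %||% plan$seed)
}
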