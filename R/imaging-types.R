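# Frame containers and their file formats.
#
# RGB frames are stored row-major as H x W x 3 arrays, either in the raw
# 0..255 camera range or in the unit interval after model preprocessing.
# Thermal frames are H x W matrices of per-pixel temperature in degC; the
# canonical on-disk form is a plain CSV grid (single-channel TIFF is also
# read). Emissivity and acquisition height are carried as metadata only --
# no radiometric re-computation is performed.

#' RGB image container
#'
#' @param pixels Numeric H x W x 3 array. `range = "raw"` means 0--255
#'   intensities, `"unit"` means values in `[0, 1]`.
#' @param range Declared value range.
#' @param color_calibrated Has a color-checker correction been applied?
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, range = c("raw", "unit"),
                      color_calibrated = FALSE) {
  range <- match.arg(range)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_invalid("pixels must be an H x W x 3 array (got dim ",
                 paste(dim(pixels), collapse = "x"), ")")
  }
  check_finite(as.vector(pixels), "pixels")
  hi <- if (range == "raw") 255 else 1
  if (min(pixels) < 0 || max(pixels) > hi) {
    stop_invalid("pixel values outside declared ", range,
                 " range [0, ", hi, "]")
  }
  structure(list(pixels = pixels, range = range,
                 color_calibrated = color_calibrated),
            class = "rgb_image")
}

#' Thermal frame container
#'
#' @param temps_c Numeric H x W matrix of per-pixel temperature, degC.
#' @param emissivity Emissivity the sensor was set to (metadata).
#' @param height_m Acquisition height above canopy in meters (metadata).
#' @param acquired_at Optional acquisition timestamp.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(temps_c, emissivity = 0.9, height_m = 1.05,
                          acquired_at = NULL) {
  if (!is.matrix(temps_c) || nrow(temps_c) < 1 || ncol(temps_c) < 1) {
    stop_invalid("temps_c must be a non-empty numeric matrix")
  }
  check_finite(as.vector(temps_c), "temps_c")
  structure(list(temps_c = temps_c, emissivity = emissivity,
                 height_m = height_m, acquired_at = acquired_at),
            class = "thermal_frame")
}

#' Region set for leaf temperature extraction
#'
#' Exactly three independent leaf regions over one frame, kept pairwise
#' disjoint so the three-region average is well defined.
#'
#' @param masks List of exactly three logical H x W matrices.
#' @return An object of class `region_set`.
#' @export
region_set <- function(masks) {
  if (length(masks) != 3L) {
    stop_invalid("a region set holds exactly 3 regions (got ",
                 length(masks), ")", class = "cwsifusion_region_error")
  }
  d <- dim(masks[[1]])
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.logical(m) || !identical(dim(m), d)) {
      stop_invalid("region ", i, " is not a logical mask of matching size",
                   class = "cwsifusion_region_error")
    }
    if (!any(m)) {
      stop_invalid("region ", i, " is empty",
                   class = "cwsifusion_region_error")
    }
  }
  overlap <- (masks[[1]] & masks[[2]]) | (masks[[1]] & masks[[3]]) |
    (masks[[2]] & masks[[3]])
  if (any(overlap)) {
    stop_invalid("regions must be pairwise disjoint",
                 class = "cwsifusion_region_error")
  }
  structure(list(masks = masks), class = "region_set")
}

#' Leaf temperature by three-region averaging
#'
#' Local temperature variation and single-pixel noise are damped by
#' averaging three independent leaf regions: the mean temperature of each
#' region is computed first, and the leaf temperature is the arithmetic
#' mean of the three region means. Note this is *not* the pooled pixel
#' mean -- a large region carries no more weight than a small one.
#'
#' @param frame A [thermal_frame()].
#' @param regions A [region_set()] over the same frame geometry.
#' @return List with `region_means` (length 3) and `leaf_temp_c`.
#' @export
extract_leaf_temperature <- function(frame, regions) {
  stopifnot(inherits(frame, "thermal_frame"),
            inherits(regions, "region_set"))
  if (!identical(dim(regions$masks[[1]]), dim(frame$temps_c))) {
    stop_invalid("region masks (",
                 paste(dim(regions$masks[[1]]), collapse = "x"),
                 ") do not match frame (",
                 paste(dim(frame$temps_c), collapse = "x"), ")",
                 class = "cwsifusion_region_error")
  }
  region_means <- vapply(regions$masks,
                         function(m) mean(frame$temps_c[m]), numeric(1))
  list(region_means = region_means, leaf_temp_c = mean(region_means))
}

# ---- file formats -----------------------------------------------------

#' Read and write RGB images
#'
#' PNG/JPEG/TIFF via EBImage. Images are returned in the raw 0--255 range.
#'
#' @param path Image file path.
#' @return [read_rgb_image()] returns an `rgb_image`.
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)      # width x height x channels, 0..1
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  px <- aperm(dat, c(2, 1, 3)) * 255
  rgb_image(pmin(pmax(px, 0), 255), range = "raw")
}

#' @rdname read_rgb_image
#' @param image An `rgb_image` to write (format from file extension).
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  if (image$range == "raw") px <- px / 255
  EBImage::writeImage(EBImage::Image(aperm(px, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Read and write thermal frames
#'
#' The canonical text format is a headerless CSV grid of per-pixel degC
#' (one row per image row). Single-channel TIFF is also accepted on read.
#'
#' @param path File path (`.csv`, `.tif`, `.tiff`).
#' @param emissivity,height_m Metadata attached on read.
#' @return [read_thermal_frame()] returns a `thermal_frame`.
#' @export
read_thermal_frame <- function(path, emissivity = 0.9, height_m = 1.05) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    dat <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(dat)) == 3L) dat <- dat[, , 1]
    m <- t(dat)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
  }
  thermal_frame(m, emissivity = emissivity, height_m = height_m)
}

#' @rdname read_thermal_frame
#' @param frame A `thermal_frame` to write as a CSV grid.
#' @export
write_thermal_frame <- function(frame, path) {
  stopifnot(inherits(frame, "thermal_frame"))
  utils::write.table(frame$temps_c, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- region annotations ------------------------------------------------

# Regions travel as JSON: a list of three shapes in 0-based image
# coordinates (x = column, y = row), rectangles half-open in both axes.

rasterize_region <- function(shape, h, w) {
  if (identical(shape$type, "rect")) {
    rows <- seq_len(h) - 1L
    cols <- seq_len(w) - 1L
    outer(rows >= shape$y & rows < shape$y + shape$height,
          cols >= shape$x & cols < shape$x + shape$width, `&`)
  } else if (identical(shape$type, "polygon")) {
    v <- do.call(rbind, lapply(shape$vertices, as.numeric))
    cx <- rep(seq_len(w) - 0.5, each = h)   # pixel centers, 0-based coords
    cy <- rep(seq_len(h) - 0.5, times = w)
    inside <- pracma::inpolygon(cx, cy, v[, 1], v[, 2], boundary = TRUE)
    matrix(inside, nrow = h, ncol = w)
  } else {
    stop_invalid("unknown region type: ", shape$type %||% "<missing>",
                 class = "cwsifusion_region_error")
  }
}

#' Read and write region annotations
#'
#' Regions are stored as a JSON array of three shapes, each either
#' `{"type": "rect", "x", "y", "width", "height"}` or
#' `{"type": "polygon", "vertices": [[x, y], ...]}`, in 0-based image
#' coordinates (x = column), rectangles half-open.
#'
#' @param path JSON file path.
#' @param dim Frame dimensions `c(H, W)` to rasterize against.
#' @return A [region_set()].
#' @export
read_region_set <- function(path, dim) {
  shapes <- jsonlite::read_json(path, simplifyVector = FALSE)
  region_set(lapply(shapes, rasterize_region, h = dim[1], w = dim[2]))
}

#' @rdname read_region_set
#' @param shapes List of shape descriptors to write.
#' @export
write_region_shapes <- function(shapes, path) {
  jsonlite::write_json(shapes, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
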