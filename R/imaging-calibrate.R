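# Color-checker calibration and photometric preprocessing.
#
# A 24-patch reference checker placed in the frame anchors an affine color
# correction: the matrix minimizing the least-squares difference between
# the measured patch colors and their reference values is fitted once and
# applied to every pixel. Gamma correction and (luminance) histogram
# equalization then balance brightness; excess-green + Otsu separates
# vegetation from soil background.

#' Color checker observation
#'
#' @param observed 24 x 3 matrix of measured patch intensities (0--255).
#' @param reference 24 x 3 matrix of corresponding reference values
#'   (defaults to [colorchecker_reference()]).
#' @return An object of class `color_checker_observation`.
#' @export
color_checker_observation <- function(observed,
                                      reference = colorchecker_reference()) {
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  if (!identical(dim(observed), dim(reference))) {
    stop_invalid("observed and reference patch matrices differ in shape")
  }
  if (ncol(observed) != 3L) stop_invalid("patches must have 3 color channels")
  if (nrow(observed) != 24L) {
    stop_invalid("a full checker has 24 patches (got ", nrow(observed), ")")
  }
  check_finite(as.vector(observed), "observed")
  structure(list(observed = observed, reference = reference),
            class = "color_checker_observation")
}

#' Classic 24-patch checker reference colors
#'
#' Nominal sRGB coordinates of the classic 24-patch reference target,
#' rows in reading order (dark skin ... black).
#'
#' @return A 24 x 3 numeric matrix, 0--255 scale.
#' @export
colorchecker_reference <- function() {
  m <- matrix(c(
    115,  82,  68,  194, 150, 130,   98, 122, 157,   87, 108,  67,
    133, 128, 177,  103, 189, 170,  214, 126,  44,   80,  91, 166,
    193,  90,  99,   94,  60, 108,  157, 188,  64,  224, 163,  46,
     56,  61, 150,   70, 148,  73,  175,  54,  60,  231, 199,  31,
    187,  86, 149,    8, 133, 161,  243, 243, 242,  200, 200, 200,
    160, 160, 160,  122, 122, 121,   85,  85,  85,   52,  52,  52),
    ncol = 3, byrow = TRUE)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Fit an affine color correction from checker patches
#'
#' Least-squares fit of the affine map (3 x 3 linear part plus offset)
#' taking observed patch colors to their reference values.
#'
#' @param obs A [color_checker_observation()].
#' @return An object of class `correction_matrix`: list with `matrix`
#'   (3 x 4, last column the offset) and `residual_ss`.
#' @export
fit_color_correction <- function(obs) {
  stopifnot(inherits(obs, "color_checker_observation"))
  X <- cbind(obs$observed, 1)
  qx <- qr(X)
  if (qx$rank < 4L) {
    stop_invalid("checker observations are rank-deficient; patches do not ",
                 "span color space", class = "cwsifusion_fit_error")
  }
  B <- qr.coef(qx, obs$reference)           # 4 x 3
  resid <- obs$reference - X %*% B
  structure(list(matrix = t(B), residual_ss = sum(resid^2)),
            class = "correction_matrix")
}

#' Apply a color correction to an image
#'
#' Per-pixel affine transform, clipped to the raw 0--255 range; the result
#' is marked color-calibrated.
#'
#' @param image A raw-range [rgb_image()].
#' @param m A `correction_matrix` from [fit_color_correction()].
#' @return A corrected `rgb_image`.
#' @export
apply_color_correction <- function(image, m) {
  stopifnot(inherits(image, "rgb_image"), inherits(m, "correction_matrix"))
  if (image$range != "raw") stop_invalid("expected a raw-range image")
  d <- dim(image$pixels)
  P <- cbind(matrix(image$pixels, ncol = 3L), 1)
  out <- P %*% t(m$matrix)
  out <- pmin(pmax(out, 0), 255)
  rgb_image(array(out, d), range = "raw", color_calibrated = TRUE)
}

#' Gamma correction
#'
#' `out = 255 * (in/255)^gamma` per channel on a raw-range image.
#'
#' @param image A raw-range [rgb_image()].
#' @param gamma Positive exponent; 1 is the identity.
#' @return A gamma-corrected `rgb_image`.
#' @export
gamma_correct <- function(image, gamma) {
  stopifnot(inherits(image, "rgb_image"))
  check_finite(gamma, "gamma")
  if (gamma <= 0) stop_invalid("gamma must be > 0 (got ", gamma, ")")
  if (image$range != "raw") stop_invalid("expected a raw-range image")
  px <- 255 * (image$pixels / 255)^gamma
  rgb_image(px, range = "raw", color_calibrated = image$color_calibrated)
}

luminance255 <- function(pixels) {
  d <- dim(pixels)
  matrix(0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
           0.114 * pixels[, , 3], d[1], d[2])
}

#' Histogram equalization on the luminance channel
#'
#' Classic CDF remapping applied to the luminance channel only; each
#' pixel's RGB triple is rescaled by the luminance gain so chrominance is
#' preserved and hues do not shift.
#'
#' @param image A raw-range [rgb_image()].
#' @return An equalized `rgb_image`.
#' @export
equalize_histogram <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$range != "raw") stop_invalid("expected a raw-range image")
  y <- round(luminance255(image$pixels))
  counts <- tabulate(as.vector(y) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(y)
  lut <- if (n > cdf_min) {
    round((cdf - cdf_min) / (n - cdf_min) * 255)
  } else {
    0:255   # constant image: leave levels alone
  }
  y_new <- matrix(lut[as.vector(y) + 1L], nrow = nrow(y))
  gain <- (y_new + 1e-8) / (y + 1e-8)
  px <- image$pixels * as.vector(gain)   # recycles over channels
  rgb_image(pmin(pmax(px, 0), 255), range = "raw",
            color_calibrated = image$color_calibrated)
}

#' Vegetation foreground mask
#'
#' Separates vegetation from background with the excess-green index
#' `ExG = 2G - R - B` thresholded by Otsu's method. The method is
#' pluggable via `index_fun` for canopies where excess green is not the
#' right discriminant.
#'
#' @param image An [rgb_image()] (color-calibrated input recommended).
#' @param index_fun Function mapping an H x W x 3 unit-range array to an
#'   H x W score matrix (higher = more vegetation).
#' @return Logical H x W matrix with attribute `degenerate` (TRUE when the
#'   index has no contrast and the mask is all-FALSE or all-TRUE).
#' @export
separate_foreground <- function(image,
                                index_fun = function(px)
                                  2 * px[, , 2] - px[, , 1] - px[, , 3]) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  if (image$range == "raw") px <- px / 255
  score <- index_fun(px)
  rng <- range(score)
  if (diff(rng) < 1e-8) {
    mask <- matrix(FALSE, nrow(score), ncol(score))
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  scaled <- (score - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
  mask <- scaled > th
  attr(mask, "degenerate") <- !any(mask) || all(mask)
  mask
}

#' Preprocess a frame for the fusion model
#'
#' Resizes to the model's square input (bilinear) and normalizes to the
#' unit interval by dividing by 255. RGB frames become `side x side x 3`
#' arrays; thermal frames are first min--max scaled to 0--255 per frame
#' (the frame minimum and maximum are kept as attributes so temperature is
#' recoverable) and become `side x side x 1` arrays.
#'
#' @param x An [rgb_image()] or [thermal_frame()].
#' @param side Output spatial side in pixels.
#' @return Numeric array in `[0, 1]`; for thermal input, attributes
#'   `temp_min`, `temp_max` and `degenerate` are set.
#' @export
preprocess_for_model <- function(x, side = 128L) {
  if (inherits(x, "rgb_image")) {
    px <- x$pixels
    if (x$range == "raw") px <- px / 255
    img <- EBImage::resize(EBImage::Image(aperm(px, c(2, 1, 3)),
                                          colormode = "Color"),
                           w = side, h = side)
    out <- aperm(EBImage::imageData(img), c(2, 1, 3))
    return(pmin(pmax(out, 0), 1))
  }
  if (inherits(x, "thermal_frame")) {
    t_min <- min(x$temps_c); t_max <- max(x$temps_c)
    degenerate <- (t_max - t_min) < 1e-12
    scaled <- if (degenerate) {
      matrix(0, nrow(x$temps_c), ncol(x$temps_c))
    } else {
      (x$temps_c - t_min) / (t_max - t_min)
    }
    img <- EBImage::resize(EBImage::Image(t(scaled)), w = side, h = side)
    out <- array(t(EBImage::imageData(img)), c(side, side, 1L))
    out <- pmin(pmax(out, 0), 1)
    attr(out, "temp_min") <- t_min
    attr(out, "temp_max") <- t_max
    attr(out, "degenerate") <- degenerate
    return(out)
  }
  stop_invalid("preprocess_for_model expects an rgb_image or thermal_frame")
}

#' Quality-control filter for frames
#'
#' Programmatic stand-ins for visual culling of unusable frames: a
#' foreground-fraction bound rejects frames whose leaf regions are not
#' distinguishable, a variance-of-Laplacian blur score rejects out-of-focus
#' frames, and an optional exclusion mask rejects frames contaminated by
#' non-crop objects. Every rejection is logged with its rule id.
#'
#' @param frames List of [rgb_image()] objects (or lists with an `$rgb`
#'   element, e.g. synthetic samples).
#' @param min_foreground_frac Minimum vegetation fraction (rule
#'   `"foreground"`).
#' @param min_laplacian_var Minimum variance of the Laplacian of luminance
#'   (rule `"focus"`); blurred frames fall below it.
#' @param exclusion_masks Optional list of logical masks marking non-crop
#'   pixels; any overlap above `max_exclusion_frac` rejects (rule
#'   `"exclusion"`).
#' @param max_exclusion_frac Tolerated excluded-pixel fraction.
#' @return List with `retained` (indices), `frames` (retained frames) and
#'   `log` (data frame: `index`, `rule`, `score`).
#' @export
qc_filter <- function(frames, min_foreground_frac = 0.02,
                      min_laplacian_var = 30,
                      exclusion_masks = NULL, max_exclusion_frac = 0) {
  log <- data.frame(index = integer(), rule = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  keep <- logical(length(frames))
  for (i in seq_along(frames)) {
    img <- frames[[i]]
    if (!inherits(img, "rgb_image") && !is.null(img$rgb)) img <- img$rgb
    stopifnot(inherits(img, "rgb_image"))
    fg <- separate_foreground(img)
    fg_frac <- mean(fg)
    blur <- laplacian_variance(img)
    excl <- if (!is.null(exclusion_masks)) mean(exclusion_masks[[i]]) else 0
    if (fg_frac < min_foreground_frac || isTRUE(attr(fg, "degenerate"))) {
      log <- rbind(log, data.frame(index = i, rule = "foreground",
                                   score = fg_frac))
    } else if (blur < min_laplacian_var) {
      log <- rbind(log, data.frame(index = i, rule = "focus", score = blur))
    } else if (excl > max_exclusion_frac) {
      log <- rbind(log, data.frame(index = i, rule = "exclusion",
                                   score = excl))
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = which(keep), frames = frames[keep], log = log)
}

#' Variance-of-Laplacian focus score
#'
#' @param image An [rgb_image()].
#' @return Variance of the Laplacian-filtered luminance (0--255 scale);
#'   low values indicate blur.
#' @export
laplacian_variance <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  if (image$range == "unit") px <- px * 255
  y <- luminance255(px)
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- EBImage::imageData(EBImage::filter2(EBImage::Image(t(y)), k))
  stats::var(as.vector(lap))
}

#' Write a QC rejection log as JSON lines
#'
#' @param log Rejection log from [qc_filter()].
#' @param path Output path.
#' @export
write_qc_log <- function(log, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
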