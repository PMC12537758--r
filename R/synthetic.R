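# Seeded synthetic data generator.
#
# Emulates the acquisition stack the diagnostic models assume: five soil
# moisture treatments defined by VWC band, paired RGB/thermal frames with
# elliptical leaf blobs on a soil background, three disjoint annotated
# leaf regions per frame, stage-conditional growth indicators, and
# per-sample weather. Directionality follows crop water stress
# physiology -- droughted canopies run hotter and yellower, waterlogged
# ones cooler and darker -- with magnitudes that are configuration, not
# claims about any particular cultivar. A single `separation` dial
# scales every class-conditional deviation, so downstream classifiers
# can be tested from chance level (separation 0) to near-perfect
# recovery (default 1).

#' Generator configuration
#'
#' @param n_per_class Named counts per 5-level class; the default follows
#'   the 1:1:2:1:1 treatment design with 50 samples per unit.
#' @param stages Growth stages to emit (cycled over samples).
#' @param image_side Rendered frame side in px (before any model
#'   resizing; frames are rendered larger than the model input so the
#'   real preprocessing path is exercised).
#' @param leaf_temp_by_class Mean leaf temperature per class, degC.
#' @param leaf_color_by_class 5 x 3 matrix of leaf RGB color per class
#'   (0--255 rows in SD, D, O, W, SW order).
#' @param background_color Soil RGB color.
#' @param thermal_noise_sd Pixel noise of the thermal frame, degC.
#' @param rgb_noise_sd Pixel noise of the RGB frame, 0--255 scale.
#' @param indicator_noise_sd Named per-feature draw sd.
#' @param separation Scales all class-conditional deviations from their
#'   across-class mean; 0 removes class signal entirely.
#' @param air_temp_c,air_temp_sd,rh_range Weather draw parameters.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_class = design_counts(50L),
                             stages = c("early", "tuber", "late"),
                             image_side = 160L,
                             leaf_temp_by_class = c(SD = 33, D = 31, O = 28,
                                                    W = 26, SW = 24),
                             leaf_color_by_class = default_leaf_colors(),
                             background_color = c(120, 85, 60),
                             thermal_noise_sd = 0.15,
                             rgb_noise_sd = 6,
                             indicator_noise_sd = c(stem_length = 1.5,
                                                    ndvi = 0.02, cf = 0.02,
                                                    spad = 0.8,
                                                    leaf_temp_c = 0.3),
                             separation = 1,
                             air_temp_c = 25, air_temp_sd = 1,
                             rh_range = c(45, 85),
                             seed = 1L) {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% stress_levels5())) {
    stop_invalid("n_per_class must be named by the 5-level classes")
  }
  if (any(n_per_class < 0)) stop_invalid("n_per_class must be >= 0")
  if (image_side < 32) stop_invalid("image_side too small to render leaves")
  check_finite(leaf_temp_by_class, "leaf_temp_by_class")
  check_range(rh_range, 0, 100, "rh_range")
  structure(as.list(environment()), class = "generator_config")
}

#' @rdname generator_config
#' @export
default_leaf_colors <- function() {
  m <- rbind(SD = c(150, 140, 60), D = c(115, 150, 70),
             O = c(70, 150, 60), W = c(50, 130, 70),
             SW = c(40, 110, 90))
  colnames(m) <- c("R", "G", "B")
  m
}

# class-conditional indicator means: stage base + class effect (scaled by
# the separation dial around the class-mean).
indicator_means <- function(stage, class_idx, separation) {
  stage_base <- switch(stage, early = 35, tuber = 70, late = 95)
  eff <- function(v) mean(v) + separation * (v - mean(v))
  stem <- eff(c(-12, -5, 0, -3, -8))[class_idx] + stage_base
  ndvi <- eff(c(0.55, 0.65, 0.80, 0.74, 0.62))[class_idx]
  cf <- eff(c(0.58, 0.68, 0.78, 0.74, 0.66))[class_idx]
  spad <- eff(c(28, 34, 42, 39, 33))[class_idx]
  c(stem_length = stem, ndvi = ndvi, cf = cf, spad = spad)
}

# Three disjoint elliptical leaves; returns list of logical masks.
leaf_ellipses <- function(side, size_scale = 1) {
  centers <- rbind(c(0.28, 0.30), c(0.30, 0.72), c(0.72, 0.50)) * side
  radii <- rbind(c(0.13, 0.10), c(0.10, 0.14), c(0.15, 0.12)) * side *
    size_scale
  X <- matrix(rep(seq_len(side), each = side), side)   # column index
  Y <- matrix(rep(seq_len(side), times = side), side)  # row index
  lapply(1:3, function(i) {
    ((X - centers[i, 2]) / radii[i, 1])^2 +
      ((Y - centers[i, 1]) / radii[i, 2])^2 <= 1
  })
}

#' Generate a synthetic paired dataset
#'
#' Draws one sample per requested class slot: soil VWC uniform within the
#' class band, weather, a thermal frame (background at air temperature,
#' leaf pixels at the class leaf temperature, Gaussian pixel noise), an
#' RGB frame (soil background, class-colored leaf ellipses), three
#' disjoint leaf region annotations, the exact foreground mask, and a
#' stage-conditional indicator record including measured leaf temperature
#' and the resulting CWSI.
#'
#' @param config A [generator_config()].
#' @return List with `samples` (list of `synthetic_sample` objects) and
#'   `manifest` (one data frame row per sample).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  bands <- stress_vwc_bands()
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n <- length(classes)
  stages <- rep(config$stages, length.out = n)
  side <- config$image_side
  sep <- config$separation
  leaf_t_mean <- mean(config$leaf_temp_by_class)
  leaf_cols_mean <- colMeans(config$leaf_color_by_class)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    ci <- match(cl, stress_levels5())
    band <- bands[bands$class == cl, ]
    vwc <- stats::runif(1, band$lo, band$hi)
    t_a <- stats::rnorm(1, config$air_temp_c, config$air_temp_sd)
    rh <- stats::runif(1, config$rh_range[1], config$rh_range[2])
    leaf_t <- leaf_t_mean + sep * (config$leaf_temp_by_class[[cl]] -
                                     leaf_t_mean)
    leaf_col <- leaf_cols_mean + sep * (config$leaf_color_by_class[cl, ] -
                                          leaf_cols_mean)

    masks <- leaf_ellipses(side)
    fg <- masks[[1]] | masks[[2]] | masks[[3]]

    temps <- matrix(t_a, side, side)
    temps[fg] <- leaf_t
    if (config$thermal_noise_sd > 0) {
      temps <- temps + stats::rnorm(side * side, 0,
                                    config$thermal_noise_sd)
    }

    px <- array(0, c(side, side, 3))
    for (ch in 1:3) {
      plane <- matrix(config$background_color[ch], side, side)
      plane[fg] <- leaf_col[ch]
      px[, , ch] <- plane
    }
    if (config$rgb_noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, config$rgb_noise_sd)
    }
    px <- pmin(pmax(px, 0), 255)

    mu <- indicator_means(stages[i], ci, sep)
    nsd <- config$indicator_noise_sd
    leaf_t_meas <- leaf_t + stats::rnorm(1, 0, nsd[["leaf_temp_c"]])
    weather <- weather_observation(t_a, rh)
    soil <- soil_moisture_reading(vwc, depth_cm = 20)
    cwsi <- compute_cwsi(leaf_t_meas, weather, soil)$cwsi
    indicators <- data.frame(
      stage = stages[i],
      stem_length = stats::rnorm(1, mu[["stem_length"]],
                                 nsd[["stem_length"]]),
      ndvi = stats::rnorm(1, mu[["ndvi"]], nsd[["ndvi"]]),
      cf = stats::rnorm(1, mu[["cf"]], nsd[["cf"]]),
      spad = stats::rnorm(1, mu[["spad"]], nsd[["spad"]]),
      leaf_temp_c = leaf_t_meas, cwsi = cwsi, label = cl
    )
    samples[[i]] <- structure(list(
      id = sprintf("s%04d", i),
      rgb = rgb_image(px, range = "raw"),
      thermal = thermal_frame(temps),
      regions = region_set(masks),
      truth_mask = fg,
      indicators = indicators,
      weather = weather, soil = soil,
      truth_label5 = cl,
      truth_label3 = map_5_to_3(cl),
      stage = stages[i],
      truth_leaf_temp_c = leaf_t
    ), class = "synthetic_sample")
    rows[[i]] <- cbind(data.frame(sample_id = samples[[i]]$id,
                                  label5 = cl,
                                  label3 = samples[[i]]$truth_label3,
                                  vwc_pct = vwc, air_temp_c = t_a,
                                  rel_humidity_pct = rh),
                       indicators[, setdiff(names(indicators), "label")])
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}

#' Generate a weather series
#'
#' Hourly air temperature on a sinusoidal diurnal band plus noise, and
#' uniform relative humidity draws.
#'
#' @param n Number of observations (0 gives an empty series).
#' @param seed RNG seed.
#' @param t_base,t_amplitude Mean and diurnal half-range of air
#'   temperature, degC.
#' @param rh_range Relative humidity range, percent.
#' @param noise_sd Additive temperature noise, degC.
#' @return Data frame with `hour`, `air_temp_c`, `rel_humidity_pct`.
#' @export
generate_weather_series <- function(n, seed = 1L, t_base = 25,
                                    t_amplitude = 4,
                                    rh_range = c(30, 100),
                                    noise_sd = 0.5) {
  if (n < 0) stop_invalid("n must be >= 0")
  if (n == 0) {
    return(data.frame(hour = integer(0), air_temp_c = numeric(0),
                      rel_humidity_pct = numeric(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hour <- seq_len(n) - 1L
  t_a <- t_base + t_amplitude * sin(2 * pi * hour / 24) +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  rh <- stats::runif(n, rh_range[1], rh_range[2])
  data.frame(hour = hour, air_temp_c = t_a, rel_humidity_pct = rh)
}

transform_rgb_affine <- function(pixels, m34) {
  d <- dim(pixels)
  out <- cbind(matrix(pixels, ncol = 3L), 1) %*% t(m34)
  array(pmin(pmax(out, 0), 255), d)
}

#' Degrade a synthetic sample
#'
#' Applies a controlled degradation to the RGB frame while leaving the
#' ground truth untouched, to exercise calibration and QC screens:
#' `"blur"` (Gaussian, sigma = magnitude px), `"occlusion"` (a gray block
#' covering `magnitude` fraction of the frame), or `"color-cast"` (a
#' known affine color transform of strength `magnitude`; the matrix used
#' is attached as attribute `cast_matrix`). Magnitude 0 is the identity.
#'
#' @param sample A `synthetic_sample`.
#' @param kind Degradation kind.
#' @param magnitude Degradation strength.
#' @return The degraded `synthetic_sample`.
#' @export
degrade_image <- function(sample, kind = c("blur", "occlusion",
                                           "color-cast"),
                          magnitude = 1) {
  if (!kind[1] %in% c("blur", "occlusion", "color-cast")) {
    stop_invalid("unknown degradation kind: ", kind[1])
  }
  kind <- match.arg(kind)
  stopifnot(inherits(sample, "synthetic_sample"))
  check_finite(magnitude, "magnitude")
  if (magnitude < 0) stop_invalid("magnitude must be >= 0")
  if (magnitude == 0) return(sample)
  px <- sample$rgb$pixels
  if (kind == "blur") {
    img <- EBImage::gblur(EBImage::Image(aperm(px / 255, c(2, 1, 3)),
                                         colormode = "Color"),
                          sigma = magnitude)
    px <- pmin(pmax(aperm(EBImage::imageData(img), c(2, 1, 3)) * 255,
                    0), 255)
  } else if (kind == "occlusion") {
    side <- dim(px)[1]
    block <- max(1L, round(side * sqrt(magnitude)))
    px[seq_len(block), seq_len(block), ] <- 128
  } else {
    m <- cbind(diag(c(1 + 0.3 * magnitude, 1 - 0.1 * magnitude,
                      1 - 0.25 * magnitude)),
               c(10, -5, 8) * magnitude)
    px <- transform_rgb_affine(px, m)
    attr(px, "cast_matrix") <- m
  }
  cast <- attr(px, "cast_matrix")
  sample$rgb <- rgb_image(array(px, dim(sample$rgb$pixels)),
                          range = "raw")
  if (!is.null(cast)) attr(sample$rgb, "cast_matrix") <- cast
  sample
}

#' Convert samples to fusion-model arrays
#'
#' Runs every sample through [preprocess_for_model()] and stacks the
#' results into batch arrays ready for [train_fusion()].
#'
#' @param samples List of `synthetic_sample` objects.
#' @param side Model input side.
#' @param scheme `"3"` or `"5"`: which label scheme to attach.
#' @return List with `rgb` (N x side x side x 3), `thermal`
#'   (N x side x side x 1), `labels`.
#' @export
samples_to_arrays <- function(samples, side = 128L,
                              scheme = c("3", "5")) {
  scheme <- match.arg(scheme)
  n <- length(samples)
  rgb <- array(0, c(n, side, side, 3))
  th <- array(0, c(n, side, side, 1))
  for (i in seq_len(n)) {
    rgb[i, , , ] <- preprocess_for_model(samples[[i]]$rgb, side)
    th[i, , , ] <- preprocess_for_model(samples[[i]]$thermal, side)
  }
  labels <- vapply(samples, function(s)
    if (scheme == "3") s$truth_label3 else s$truth_label5, character(1))
  list(rgb = rgb, thermal = th, labels = labels)
}

#' Write a generated dataset to disk
#'
#' Layout: `images/` (PNG for RGB, CSV grid for thermal), `regions/`
#' (run-length JSON masks, exact for the elliptical leaves),
#' `tables/manifest.csv` and `tables/indicators.csv`.
#'
#' @param ds Result of [generate_dataset()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  for (d in file.path(dir, c("images", "regions", "tables"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- ds$manifest
  manifest$rgb_path <- file.path("images",
                                 paste0(manifest$sample_id, "_rgb.png"))
  manifest$thermal_path <- file.path("images",
                                     paste0(manifest$sample_id,
                                            "_thermal.csv"))
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    write_rgb_image(s$rgb, file.path(dir, manifest$rgb_path[i]))
    write_thermal_frame(s$thermal, file.path(dir, manifest$thermal_path[i]))
    write_region_masks(s$regions,
                       file.path(dir, "regions", paste0(s$id, ".json")))
  }
  utils::write.csv(manifest, file.path(dir, "tables", "manifest.csv"),
                   row.names = FALSE)
  ind <- do.call(rbind, lapply(ds$samples, function(s) s$indicators))
  ind$sample_id <- manifest$sample_id
  utils::write.csv(ind, file.path(dir, "tables", "indicators.csv"),
                   row.names = FALSE)
  invisible(dir)
}
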