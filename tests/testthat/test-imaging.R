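# Frame handling, calibration, preprocessing and QC.

test_that("leaf temperature is the mean of region means, not pixel-pooled", {
  temps <- matrix(20, 12, 12)
  masks <- list(matrix(FALSE, 12, 12), matrix(FALSE, 12, 12),
                matrix(FALSE, 12, 12))
  masks[[1]][1:2, 1:2] <- TRUE
  masks[[2]][5:6, 5:6] <- TRUE
  masks[[3]][9:10, 9:10] <- TRUE
  rs <- region_set(masks)
  expect_equal(extract_leaf_temperature(thermal_frame(temps), rs)$leaf_temp_c,
               20)

  temps[masks[[1]]] <- 20; temps[masks[[2]]] <- 22; temps[masks[[3]]] <- 24
  expect_equal(extract_leaf_temperature(thermal_frame(temps), rs)$leaf_temp_c,
               22)

  # unequal region sizes: 1, 1 and 14 pixels with means 10, 10, 16.
  # region-mean averaging gives 12; a pixel-pooled mean would give 15.25.
  m2 <- list(matrix(FALSE, 12, 12), matrix(FALSE, 12, 12),
             matrix(FALSE, 12, 12))
  m2[[1]][1, 1] <- TRUE
  m2[[2]][3, 3] <- TRUE
  m2[[3]][6:12, 1:2] <- TRUE
  m2[[3]] <- m2[[3]] & !(m2[[1]] | m2[[2]])
  temps2 <- matrix(0, 12, 12)
  temps2[m2[[1]]] <- 10; temps2[m2[[2]]] <- 10; temps2[m2[[3]]] <- 16
  res <- extract_leaf_temperature(thermal_frame(temps2), region_set(m2))
  expect_equal(res$leaf_temp_c, 12)
  expect_equal(res$region_means, c(10, 10, 16))
})

test_that("region sets enforce their invariants", {
  ok <- list(matrix(c(TRUE, rep(FALSE, 8)), 3, 3),
             matrix(c(FALSE, TRUE, rep(FALSE, 7)), 3, 3),
             matrix(c(FALSE, FALSE, TRUE, rep(FALSE, 6)), 3, 3))
  expect_s3_class(region_set(ok), "region_set")
  expect_error(region_set(ok[1:2]), class = "cwsifusion_region_error")
  bad <- ok; bad[[2]] <- bad[[1]]   # overlap
  expect_error(region_set(bad), class = "cwsifusion_region_error")
  bad <- ok; bad[[3]][] <- FALSE    # empty
  expect_error(region_set(bad), class = "cwsifusion_region_error")
  # region outside frame geometry
  fr <- thermal_frame(matrix(20, 5, 5))
  expect_error(extract_leaf_temperature(fr, region_set(ok)),
               class = "cwsifusion_region_error")
})

test_that("color correction recovers a known affine cast to 1e-6", {
  ref <- colorchecker_reference()
  obs0 <- color_checker_observation(ref, ref)
  fit0 <- fit_color_correction(obs0)
  expect_equal(fit0$matrix[, 1:3], diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit0$matrix[, 4], rep(0, 3), tolerance = 1e-6,
               ignore_attr = TRUE)

  M <- matrix(c(1.2, 0.05, -0.02,
                0.03, 0.9, 0.04,
                -0.01, 0.02, 1.1), 3, 3, byrow = TRUE)
  b <- c(4, -6, 2)
  distorted <- ref %*% t(M) + rep(b, each = nrow(ref))
  # fitting distorted -> reference must recover the inverse transform
  fit <- fit_color_correction(color_checker_observation(distorted, ref))
  Minv <- solve(M)
  expect_equal(fit$matrix[, 1:3], Minv, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$matrix[, 4], as.vector(-Minv %*% b), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(fit$residual_ss, 1e-12)

  # least-squares optimality: fitted residual never exceeds identity's
  set.seed(42)
  noisy <- ref + matrix(rnorm(72), ncol = 3)
  fitn <- fit_color_correction(color_checker_observation(noisy, ref))
  expect_lte(fitn$residual_ss, sum((noisy - ref)^2))

  # rank-deficient patches cannot anchor a fit
  flat <- matrix(rep(c(100, 100, 100), each = 24), ncol = 3)
  expect_error(fit_color_correction(color_checker_observation(flat, ref)),
               class = "cwsifusion_fit_error")
})

test_that("applying a correction transforms pixels affinely with clipping", {
  img <- flat_rgb(c(100, 150, 200), side = 8)
  ident <- structure(list(matrix = cbind(diag(3), 0), residual_ss = 0),
                     class = "correction_matrix")
  out <- apply_color_correction(img, ident)
  expect_equal(out$pixels, img$pixels)
  expect_true(out$color_calibrated)

  m <- structure(list(matrix = cbind(2 * diag(3), c(10, 0, -500)),
                      residual_ss = 0), class = "correction_matrix")
  out <- apply_color_correction(img, m)
  expect_equal(out$pixels[1, 1, ], c(210, 255, 0))  # clipped both ways

  black <- flat_rgb(c(0, 0, 0), side = 4)
  m0 <- structure(list(matrix = cbind(diag(3) * 1.7, 0), residual_ss = 0),
                  class = "correction_matrix")
  expect_equal(apply_color_correction(black, m0)$pixels, black$pixels)
})

test_that("calibration round-trips a distorted checker image", {
  ref <- colorchecker_reference()
  # gentle cast so no channel clips at 255 (clipping is not invertible)
  M34 <- cbind(matrix(c(0.95, 0.04, 0, 0.02, 0.85, 0.03, 0, 0.01, 0.9),
                      3, 3, byrow = TRUE), c(5, -3, 2))
  # paint the 24 patches into a 4 x 6 card, distort, fit, correct
  card <- array(0, c(4 * 8, 6 * 8, 3))
  for (i in 1:24) {
    r <- (i - 1) %/% 6; c <- (i - 1) %% 6
    for (ch in 1:3) {
      card[r * 8 + 1:8, c * 8 + 1:8, ch] <- ref[i, ch]
    }
  }
  distorted_px <- cbind(matrix(card, ncol = 3), 1) %*% t(M34)
  distorted <- rgb_image(array(pmin(pmax(distorted_px, 0), 255),
                               dim(card)))
  obs <- t(sapply(1:24, function(i) {
    r <- (i - 1) %/% 6; c <- (i - 1) %% 6
    colMeans(matrix(distorted$pixels[r * 8 + 1:8, c * 8 + 1:8, ],
                    ncol = 3))
  }))
  fit <- fit_color_correction(color_checker_observation(obs, ref))
  corrected <- apply_color_correction(distorted, fit)
  recovered <- t(sapply(1:24, function(i) {
    r <- (i - 1) %/% 6; c <- (i - 1) %% 6
    colMeans(matrix(corrected$pixels[r * 8 + 1:8, c * 8 + 1:8, ],
                    ncol = 3))
  }))
  expect_lt(max(abs(recovered - ref)), 0.5)
})

test_that("gamma correction follows the power law with fixed points", {
  img <- flat_rgb(c(64, 128, 255))
  expect_equal(gamma_correct(img, 1)$pixels, img$pixels)
  out <- gamma_correct(img, 0.5)
  expect_equal(out$pixels[1, 1, 1], 255 * (64 / 255)^0.5, tolerance = 1e-12)
  expect_equal(out$pixels[1, 1, 3], 255)   # 255 is a fixed point
  expect_equal(gamma_correct(flat_rgb(c(0, 0, 0)), 2.2)$pixels[1, 1, ],
               c(0, 0, 0))
  expect_validation_error(gamma_correct(img, 0))
  expect_validation_error(gamma_correct(img, -1))
})

test_that("histogram equalization stretches low-contrast images", {
  # low-contrast ramp confined to [100, 140]
  side <- 64
  ramp <- array(rep(seq(100, 140, length.out = side), each = side),
                c(side, side, 3))
  out <- equalize_histogram(rgb_image(ramp))
  y <- 0.299 * out$pixels[, , 1] + 0.587 * out$pixels[, , 2] +
    0.114 * out$pixels[, , 3]
  expect_gte(diff(range(y)), 0.9 * 255)

  # two-level image keeps its levels at the extremes
  two <- array(0, c(8, 8, 3)); two[5:8, , ] <- 255
  out2 <- equalize_histogram(rgb_image(two))
  expect_setequal(unique(as.vector(round(out2$pixels))), c(0, 255))

  # already uniform luminance histogram: mapping is near identity
  uni <- array(rep(0:255, each = 1), c(256, 1, 3))
  uni <- rgb_image(array(rep(uni[, , 1], 3), c(256, 1, 3)))
  out3 <- equalize_histogram(uni)
  expect_lt(max(abs(out3$pixels - uni$pixels)), 2)
})

test_that("foreground separation finds vegetation and is idempotent", {
  # pure green square on gray
  side <- 40
  px <- array(128, c(side, side, 3))
  truth <- matrix(FALSE, side, side)
  truth[11:30, 11:30] <- TRUE
  px[, , 1][truth] <- 30; px[, , 2][truth] <- 180; px[, , 3][truth] <- 40
  img <- rgb_image(px)
  mask <- separate_foreground(img)
  expect_type(mask, "logical")
  expect_gte(mean(mask == truth), 0.99)
  expect_identical(mask, separate_foreground(img))

  # no contrast: degenerate flag
  gray <- separate_foreground(flat_rgb(c(128, 128, 128)))
  expect_true(attr(gray, "degenerate"))

  # generator ground truth: IoU >= 0.9
  s <- small_dataset()$samples[[1]]
  m <- separate_foreground(s$rgb)
  iou <- sum(m & s$truth_mask) / sum(m | s$truth_mask)
  expect_gte(iou, 0.9)
})

test_that("model preprocessing hits the shape and range contract", {
  s <- small_dataset()$samples[[1]]
  arr <- preprocess_for_model(s$rgb)
  expect_equal(dim(arr), c(128, 128, 3))
  expect_gte(min(arr), 0); expect_lte(max(arr), 1)

  all_white <- preprocess_for_model(flat_rgb(c(255, 255, 255)))
  expect_true(all(all_white == 1))

  th <- preprocess_for_model(s$thermal)
  expect_equal(dim(th), c(128, 128, 1))
  expect_gte(min(th), 0); expect_lte(max(th), 1)
  # temperature recoverable from stored extremes
  expect_equal(attr(th, "temp_min"), min(s$thermal$temps_c))
  expect_equal(attr(th, "temp_max"), max(s$thermal$temps_c))

  const <- preprocess_for_model(thermal_frame(matrix(21.5, 30, 30)))
  expect_true(attr(const, "degenerate"))
  expect_equal(length(unique(as.vector(const))), 1L)
})

test_that("QC proxies retain sharp leafy frames and log rejections", {
  s <- small_dataset()$samples[[1]]
  blurred <- degrade_image(s, "blur", 6)
  flat <- flat_rgb(c(128, 128, 128), side = 160)
  res <- qc_filter(list(s$rgb, blurred$rgb, flat))
  expect_equal(res$retained, 1L)
  expect_setequal(res$log$rule, c("focus", "foreground"))
  expect_equal(res$log$index, c(2L, 3L))

  empty <- qc_filter(list())
  expect_equal(length(empty$retained), 0L)
  expect_equal(nrow(empty$log), 0L)

  log_path <- tempfile(fileext = ".jsonl")
  write_qc_log(res$log, log_path)
  lines <- readLines(log_path)
  expect_equal(length(lines), 2L)
  expect_equal(jsonlite::fromJSON(lines[1])$rule, "focus")
})

test_that("frames and regions survive a disk round trip", {
  s <- small_dataset()$samples[[2]]
  png <- tempfile(fileext = ".png")
  write_rgb_image(s$rgb, png)
  back <- read_rgb_image(png)
  expect_equal(dim(back$pixels), dim(s$rgb$pixels))
  expect_lt(mean(abs(back$pixels - s$rgb$pixels)), 1)   # 8-bit rounding

  csv <- tempfile(fileext = ".csv")
  write_thermal_frame(s$thermal, csv)
  tf <- read_thermal_frame(csv)
  expect_equal(tf$temps_c, s$thermal$temps_c, tolerance = 1e-12)
  expect_equal(tf$emissivity, 0.9)
  expect_equal(tf$height_m, 1.05)

  rj <- tempfile(fileext = ".json")
  write_region_masks(s$regions, rj)
  rs <- read_region_masks(rj)
  expect_equal(rs$masks, s$regions$masks)
})

test_that("polygon/rect region annotations rasterize as specified", {
  shapes <- list(
    list(type = "rect", x = 0, y = 0, width = 2, height = 2),
    list(type = "rect", x = 4, y = 4, width = 2, height = 3),
    list(type = "polygon",
         vertices = list(c(0, 6), c(3, 6), c(3, 8), c(0, 8)))
  )
  path <- tempfile(fileext = ".json")
  write_region_shapes(shapes, path)
  rs <- read_region_set(path, dim = c(10, 8))
  # half-open rect [0,2) x [0,2): pixels rows 1:2, cols 1:2
  expect_equal(sum(rs$masks[[1]]), 4L)
  expect_true(all(rs$masks[[1]][1:2, 1:2]))
  expect_equal(sum(rs$masks[[2]]), 6L)
  expect_true(all(rs$masks[[2]][5:7, 5:6]))
  expect_gt(sum(rs$masks[[3]]), 0)
  expect_true(all(which(rs$masks[[3]], arr.ind = TRUE)[, "col"] <= 3))
})
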