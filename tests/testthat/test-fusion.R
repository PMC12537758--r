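# Dual-branch CNN + transformer fusion classifier: structure, gradients,
# channel mask, class restructuring and Grad-CAM.

test_that("default model lands near 2.2e5 parameters and outputs softmax", {
  m <- build_fusion_model(fusion_config(n_classes = 3L))
  expect_gte(m$n_parameters, 1.5e5)
  expect_lte(m$n_parameters, 3e5)
  # direct recount from the weight arrays
  expect_equal(m$n_parameters,
               sum(vapply(m$params, length, numeric(1))))

  tm <- build_fusion_model(tiny_fusion_config())
  p <- predict_proba(tm, array(runif(16 * 16 * 3), c(16, 16, 3)),
                     array(runif(16 * 16), c(16, 16, 1)))
  expect_equal(ncol(p), 3)
  expect_equal(colnames(p), stress_levels3())
  expect_equal(rowSums(p), 1, tolerance = 1e-6, ignore_attr = TRUE)

  t5 <- build_fusion_model(tiny_fusion_config(n_classes = 5L))
  expect_equal(t5$classes, stress_levels5())
  expect_error(fusion_config(n_classes = 4L),
               class = "cwsifusion_config_error")
  expect_error(fusion_config(input_side = 100L),
               class = "cwsifusion_config_error")
  expect_error(fusion_config(n_heads = 3L),
               class = "cwsifusion_config_error")
})

test_that("same seed gives identical initial weights; inference is pure", {
  m1 <- build_fusion_model(tiny_fusion_config(seed = 11L))
  m2 <- build_fusion_model(tiny_fusion_config(seed = 11L))
  expect_identical(m1$params, m2$params)
  m3 <- build_fusion_model(tiny_fusion_config(seed = 12L))
  expect_false(identical(m1$params, m3$params))

  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  th <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(predict_proba(m1, rgb, th), predict_proba(m1, rgb, th))
})

test_that("unpreprocessed inputs are rejected at prediction time", {
  m <- build_fusion_model(tiny_fusion_config())
  raw <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  th <- array(runif(16 * 16), c(16, 16, 1))
  expect_validation_error(predict_proba(m, raw, th))
  expect_validation_error(
    predict_proba(m, array(runif(8 * 8 * 3), c(8, 8, 3)), th))
})

test_that("channel mask keeps strictly-above-threshold channels only", {
  mk <- function(means) {
    # build feature maps whose channel means are exactly `means`
    array(rep(means, each = 2 * 4 * 4), c(2, 4, 4, length(means)))
  }
  cm <- compute_channel_mask(mk(c(0.05, 0.2, 0.3)), threshold = 0.1)
  expect_equal(cm$keep, c(FALSE, TRUE, TRUE))
  expect_equal(cm$channel_means, c(0.05, 0.2, 0.3))
  expect_false(cm$degenerate)

  # boundary case: exactly 0.1 is dropped (strict inequality)
  cm2 <- compute_channel_mask(mk(c(0.1, 0.2)), threshold = 0.1)
  expect_equal(cm2$keep, c(FALSE, TRUE))

  # all-zero activations: fallback keeps the single max channel, flagged
  cm3 <- compute_channel_mask(mk(c(0, 0, 0)), threshold = 0.1)
  expect_equal(sum(cm3$keep), 1L)
  expect_true(cm3$degenerate)
})

test_that("masked channels contribute nothing to the fused vector", {
  m <- build_fusion_model(tiny_fusion_config(seed = 3L))
  rgb <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  th <- array(runif(2 * 16 * 16), c(2, 16, 16, 1))
  keep <- c(TRUE, FALSE, TRUE, FALSE)
  m$mask <- structure(list(keep = keep, channel_means = rep(1, 4),
                           threshold = 0.1, degenerate = FALSE),
                      class = "channel_mask")
  cc <- cwsifusion:::fusion_forward(m, rgb, th, cache = TRUE)
  expect_true(all(cc$g_th[, !keep] == 0))
  # zeroing the masked channels' conv3 weights leaves outputs unchanged
  m2 <- m
  m2$params$th_w3[, , , !keep] <- 0
  m2$params$th_b3[!keep] <- 0
  cc2 <- cwsifusion:::fusion_forward(m2, rgb, th)
  expect_equal(cc$proba, cc2$proba, tolerance = 1e-5)
})

test_that("5-to-3 mapping collapses extremes onto their neighbours", {
  expect_equal(map_5_to_3("O"), "OPTIMAL")
  expect_equal(map_5_to_3("SD"), "DRY_SIDE")
  expect_equal(map_5_to_3("SW"), "WET_SIDE")
  lab5 <- rep(stress_levels5(), each = 4)
  lab3 <- map_5_to_3(lab5)
  expect_length(lab3, length(lab5))           # conserves sample count
  expect_setequal(unique(lab3), stress_levels3())  # surjective
  expect_identical(lab3, map_5_to_3(lab5))    # deterministic
  expect_validation_error(map_5_to_3("XX"))
  # mapping is a configurable table
  alt <- c(SD = "DRY_SIDE", D = "OPTIMAL", O = "OPTIMAL",
           W = "OPTIMAL", SW = "WET_SIDE")
  expect_equal(map_5_to_3("D", alt), "OPTIMAL")
  expect_equal(collapse_proba_5to3(c(SD = 0.5, D = 0.1, O = 0.2,
                                     W = 0.1, SW = 0.1)),
               c(DRY_SIDE = 0.6, OPTIMAL = 0.2, WET_SIDE = 0.2))
  expect_equal(stress3_display()[["DRY_SIDE"]], "Severe Dry")
})

test_that("analytic gradients match finite differences", {
  m <- build_fusion_model(tiny_fusion_config(seed = 7L))
  set.seed(1)
  N <- 3
  rgb <- array(runif(N * 16 * 16 * 3), c(N, 16, 16, 3))
  th <- array(runif(N * 16 * 16), c(N, 16, 16, 1))
  y <- c(1L, 2L, 3L)
  loss_fn <- function(model) {
    cc <- cwsifusion:::fusion_forward(model, rgb, th)
    -mean(log(cc$proba[cbind(1:N, y)]))
  }
  cc <- cwsifusion:::fusion_forward(m, rgb, th, cache = TRUE)
  onehot <- matrix(0, N, 3); onehot[cbind(1:N, y)] <- 1
  bw <- cwsifusion:::fusion_backward(m, cc, (cc$proba - onehot) / N)
  eps <- 1e-3   # conv path is single precision; eps sized accordingly
  set.seed(2)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      if (abs(num) + abs(ana) < 1e-4) next  # below fp32 resolution
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 0.05)
    }
  }
})

test_that("branch kernels agree with the double-precision oracles", {
  set.seed(2)
  x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  ws <- list(array(rnorm(3 * 3 * 3 * 4) * .2, c(3, 3, 3, 4)),
             array(rnorm(3 * 3 * 4 * 5) * .2, c(3, 3, 4, 5)),
             array(rnorm(3 * 3 * 5 * 6) * .2, c(3, 3, 5, 6)))
  bs <- list(rnorm(4) * .1, rnorm(5) * .1, rnorm(6) * .1)
  fb <- cwsifusion:::.branch_fwd(x, ws, bs, cwsifusion:::.branch_ws_new(),
                                 TRUE)
  cur <- x
  for (l in 1:3) {
    a <- cwsifusion:::.relu_fwd(
      cwsifusion:::.conv2d_fwd(cur, ws[[l]], bs[[l]]))
    if (l == 3) a3d <- a
    cur <- cwsifusion:::.maxpool2_fwd(a)$y
  }
  expect_equal(fb$out, cur, tolerance = 1e-5)
  expect_equal(fb$a3, a3d, tolerance = 1e-5)
})

test_that("double conv/pool kernels match direct R computation", {
  set.seed(3)
  x <- array(rnorm(1 * 4 * 4 * 2), c(1, 4, 4, 2))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  b <- c(0.1, -0.2)
  y <- cwsifusion:::.conv2d_fwd(x, w, b)
  # direct same-padding correlation
  ref <- array(0, c(1, 4, 4, 2))
  for (co in 1:2) for (h in 1:4) for (wd in 1:4) {
    acc <- b[co]
    for (ci in 1:2) for (kh in 1:3) for (kw in 1:3) {
      hs <- h + kh - 2; wsd <- wd + kw - 2
      if (hs >= 1 && hs <= 4 && wsd >= 1 && wsd <= 4) {
        acc <- acc + x[1, hs, wsd, ci] * w[kh, kw, ci, co]
      }
    }
    ref[1, h, wd, co] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)

  pl <- cwsifusion:::.maxpool2_fwd(y)
  for (co in 1:2) for (h in 1:2) for (wd in 1:2) {
    expect_equal(pl$y[1, h, wd, co],
                 max(y[1, 2 * h - 1:0, 2 * wd - 1:0, co]))
  }
})

test_that("initial loss on balanced classes is near ln(K)", {
  m <- build_fusion_model(fusion_config(seed = 5L))
  set.seed(9)
  N <- 9
  rgb <- array(runif(N * 128 * 128 * 3), c(N, 128, 128, 3))
  th <- array(runif(N * 128 * 128), c(N, 128, 128, 1))
  y <- rep(1:3, each = 3)
  cc <- cwsifusion:::fusion_forward(m, rgb, th)
  loss <- -mean(log(cc$proba[cbind(1:N, y)]))
  expect_lte(loss, log(3) + 0.2)
})

test_that("a tiny model overfits a single batch to accuracy 1", {
  cfg <- tiny_fusion_config(seed = 21L)
  m <- build_fusion_model(cfg)
  set.seed(10)
  N <- 24
  cls <- rep(1:3, each = N / 3)
  rgb <- array(runif(N * 16 * 16 * 3), c(N, 16, 16, 3))
  for (i in seq_len(N)) {   # class-coded channel bias
    rgb[i, , , cls[i]] <- pmin(1, rgb[i, , , cls[i]] + 0.4)
  }
  th <- array(runif(N * 16 * 16), c(N, 16, 16, 1))
  m <- train_fusion(m, rgb, th, stress_levels3()[cls],
                    validation = "none", max_epochs = 150L)
  expect_equal(tail(m$history$train_accuracy, 1), 1)
  expect_true(m$trained)
})

test_that("training history, mask freezing and reproducibility hold", {
  cfg <- tiny_fusion_config(seed = 22L)
  set.seed(11)
  N <- 30
  cls <- rep(1:3, each = 10)
  rgb <- array(runif(N * 16 * 16 * 3), c(N, 16, 16, 3))
  for (i in seq_len(N)) rgb[i, , , cls[i]] <- 1
  th <- array(runif(N * 16 * 16), c(N, 16, 16, 1))
  labels <- stress_levels3()[cls]
  m1 <- train_fusion(build_fusion_model(cfg), rgb, th, labels,
                     max_epochs = 4L)
  m2 <- train_fusion(build_fusion_model(cfg), rgb, th, labels,
                     max_epochs = 4L)
  expect_identical(m1$params, m2$params)   # same seed, same run
  expect_identical(m1$mask$keep, m2$mask$keep)
  expect_s3_class(m1$mask, "channel_mask")
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                    names(m1$history)))
  expect_validation_error(
    train_fusion(build_fusion_model(cfg), rgb, th, labels[-1]))
  expect_validation_error(
    train_fusion(build_fusion_model(cfg), rgb, th, rep("Q", N)))
})

test_that("Grad-CAM matches the closed form on a known case", {
  # hand-checkable case: weights = spatial mean of gradients, map =
  # normalized ReLU of the weighted activation sum
  acts <- array(0, c(2, 2, 2))
  acts[, , 1] <- matrix(c(1, 0, 0, 0), 2, 2)
  acts[, , 2] <- matrix(c(0, 0, 0, 2), 2, 2)
  grads <- array(0, c(2, 2, 2))
  grads[, , 1] <- 0.5     # channel weight 0.5
  grads[, , 2] <- -1      # channel weight -1: suppressive channel
  cam <- cam_from_activations(acts, grads)
  # raw map: 0.5*acts1 - 1*acts2 -> ReLU -> [[0.5,0],[0,0]] -> /0.5
  expect_equal(cam[1, 1], 1)
  expect_equal(cam[2, 2], 0)
  expect_false(attr(cam, "degenerate"))

  camz <- cam_from_activations(acts, grads * 0)
  expect_true(attr(camz, "degenerate"))
  expect_true(all(camz == 0))
})

test_that("Grad-CAM heatmaps obey the range contract on a real model", {
  m <- build_fusion_model(tiny_fusion_config(seed = 31L))
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  th <- array(runif(16 * 16), c(16, 16, 1))
  for (br in c("rgb", "thermal")) {
    hm <- grad_cam(m, rgb, th, branch = br)
    expect_s3_class(hm, "heatmap")
    expect_equal(dim(hm$values), c(16, 16))
    expect_gte(min(hm$values), 0)
    expect_lte(max(hm$values), 1)
    if (!hm$degenerate) expect_equal(max(hm$values), 1)
    expect_true(hm$target_class %in% stress_levels3())
  }
  expect_validation_error(grad_cam(m, rgb, th, target_class = "XX"))
  csv <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  hm <- grad_cam(m, rgb, th, branch = "rgb")
  write_heatmap(hm, csv, overlay_png = png,
                image = rgb_image(rgb, range = "unit"))
  expect_true(file.exists(csv) && file.exists(png))
  vals <- as.matrix(read.csv(csv, header = FALSE))
  expect_equal(unname(vals), unname(hm$values), tolerance = 1e-6)
})

test_that("fusion models round-trip through save/load", {
  m <- build_fusion_model(tiny_fusion_config(seed = 41L))
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  th <- array(runif(16 * 16), c(16, 16, 1))
  p1 <- predict_proba(m, rgb, th)
  path <- tempfile(fileext = ".rds")
  save_fusion_model(m, path)
  m2 <- load_fusion_model(path)
  expect_equal(predict_proba(m2, rgb, th), p1)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(side$config$n_classes, 3)
  expect_equal(side$n_parameters, m$n_parameters)
})
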