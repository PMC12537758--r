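# Feature ranking, top-k selection and growth-stage classifiers.

# Published stage-wise importance table used as an external ranking input
# (leaf temperature, CWSI, stem length, CF, NDVI, SPAD per stage).
published_importances <- function() {
  list(
    early = c(leaf_temp_c = 0.246, cwsi = 0.177, stem_length = 0.174,
              cf = 0.164, ndvi = 0.139, spad = 0.101),
    tuber = c(leaf_temp_c = 0.161, cwsi = 0.271, stem_length = 0.122,
              cf = 0.125, ndvi = 0.152, spad = 0.172),
    late = c(leaf_temp_c = 0.185, cwsi = 0.265, stem_length = 0.178,
             cf = 0.089, ndvi = 0.103, spad = 0.164)
  )
}

test_that("top-4 selection reproduces the stage-wise feature sets", {
  imp <- published_importances()
  expect_equal(select_top_k(importance_ranking(imp$early), 4),
               c("leaf_temp_c", "cwsi", "stem_length", "cf"))
  expect_equal(select_top_k(importance_ranking(imp$tuber), 4),
               c("cwsi", "spad", "leaf_temp_c", "ndvi"))
  # late stage, ordered by the printed scores: CWSI, leaf temperature,
  # stem length, SPAD
  expect_equal(select_top_k(importance_ranking(imp$late), 4),
               c("cwsi", "leaf_temp_c", "stem_length", "spad"))
})

test_that("top-k breaks ties by canonical feature order", {
  sc <- setNames(rep(1 / 6, 6), indicator_features())
  expect_equal(select_top_k(importance_ranking(sc), 4),
               indicator_features()[1:4])
  sc2 <- c(a = 0.2, b = 0.4, c = 0.2, d = 0.2)
  expect_equal(select_top_k(importance_ranking(sc2), 2), c("b", "a"))
  expect_validation_error(
    select_top_k(importance_ranking(sc2), 9))
})

test_that("importance rankings are normalized and validated", {
  r <- importance_ranking(c(x = 2, y = 1, z = 1))
  expect_equal(sum(r$scores), 1)
  expect_equal(unname(r$scores[["x"]]), 0.5)
  expect_validation_error(importance_ranking(c(1, 2)))
  expect_validation_error(importance_ranking(c(a = -1, b = 2)))
})

test_that("forest ranking puts the informative feature first", {
  set.seed(12)
  n <- 60
  label <- rep(c("A", "B", "C"), each = n / 3)
  records <- data.frame(
    leaf_temp_c = rnorm(n, rep(c(25, 29, 33), each = n / 3), 0.4),
    cwsi = runif(n), stem_length = rnorm(n, 50, 5),
    cf = rnorm(n), ndvi = rnorm(n), spad = rnorm(n),
    label = label
  )
  r <- rank_features(records, seed = 42)
  expect_s3_class(r, "importance_ranking")
  expect_equal(sum(r$scores), 1, tolerance = 1e-9)
  expect_equal(names(which.max(r$scores)), "leaf_temp_c")
  expect_gt(r$scores[["leaf_temp_c"]], 0.5)

  # permutation variant also available and agrees on the winner
  rp <- rank_features(records, method = "permutation", seed = 42)
  expect_equal(names(which.max(rp$scores)), "leaf_temp_c")

  expect_validation_error(
    rank_features(transform(records, label = "A")))
})

test_that("duplicated features share importance (forest masking)", {
  set.seed(13)
  n <- 90
  label <- rep(c("A", "B", "C"), each = n / 3)
  sig <- rnorm(n, rep(c(0, 4, 8), each = n / 3), 0.5)
  base <- data.frame(f1 = sig, f2 = rnorm(n), f3 = rnorm(n),
                     label = label)
  solo <- rank_features(base, features = c("f1", "f2", "f3"), seed = 1)
  dup <- rank_features(transform(base, f1b = sig + rnorm(n, 0, 1e-9)),
                       features = c("f1", "f1b", "f2", "f3"), seed = 1)
  expect_lt(dup$scores[["f1"]], solo$scores[["f1"]])
  expect_lt(dup$scores[["f1b"]], solo$scores[["f1"]])
  expect_gt(dup$scores[["f1"]] + dup$scores[["f1b"]],
            0.8 * solo$scores[["f1"]])
})

test_that("pure-noise features rank near-uniformly over seeds", {
  set.seed(14)
  n <- 100
  records <- data.frame(matrix(rnorm(n * 6), n, 6))
  names(records) <- indicator_features()
  records$label <- rep(stress_levels5(), each = n / 5)
  ratios <- sapply(1:10, function(s) {
    sc <- rank_features(records, seed = s, ntree = 300)$scores
    max(sc) / min(sc)
  })
  expect_lt(stats::median(ratios), 2)
})

test_that("every model family learns separable stage data", {
  ind <- make_indicator_table(n_per_class = 12, seed = 31)
  feats <- select_top_k(rank_features(ind, seed = 42), 4)
  expect_true(all(feats %in% indicator_features()))
  for (kind in model_kinds()) {
    m <- fit_stage_model(kind, ind, feats, seed = 42, stage = "early")
    pred <- predict(m, ind)
    expect_equal(dim(pred$proba), c(nrow(ind), 5))
    expect_equal(unname(rowSums(pred$proba)), rep(1, nrow(ind)),
                 tolerance = 1e-6)
    expect_gte(mean(pred$label == ind$label), 0.98)
  }
  expect_error(fit_stage_model("XGB", ind, feats),
               class = "cwsifusion_config_error")
})

test_that("1-NN memorizes its training set", {
  ind <- make_indicator_table(n_per_class = 8, seed = 32)
  m <- fit_stage_model("KNN", ind, indicator_features(), seed = 42,
                       params = list(k = 1))
  expect_equal(mean(predict(m, ind)$label == ind$label), 1)
})

test_that("label-shuffled data scores in the chance band", {
  ind <- make_indicator_table(n_per_class = 10, seed = 33)
  set.seed(77)
  ind$label <- sample(ind$label)
  plan <- make_stratified_folds(ind$label, k = 5, seed = 42)
  r <- cross_validate("KNN", ind[, indicator_features()], ind$label, plan)
  expect_gte(r$mean_accuracy, 0.05)
  expect_lte(r$mean_accuracy, 0.40)
})

test_that("all families evaluate on one shared fold plan", {
  ind <- make_indicator_table(n_per_class = 10, seed = 34)
  plan <- make_stratified_folds(ind$label, k = 5, seed = 42)
  reports <- evaluate_stage_models(ind, plan, seed = 42)
  expect_named(reports, model_kinds())
  for (r in reports) {
    expect_s3_class(r, "cv_report")
    expect_gte(r$mean_accuracy, 0.9)   # separable by construction
    expect_equal(sum(r$confusion$counts), nrow(ind))
  }
  expect_validation_error(
    evaluate_stage_models(ind[0, ], plan))
})

test_that("parameter recovery: separated class means give CV accuracy >= 0.95", {
  # generator defaults separate adjacent classes by several within-class
  # standard deviations in leaf temperature (and strongly in CWSI)
  gen <- make_indicator_table(n_per_class = 12, seed = 35)
  by_class <- split(gen$leaf_temp_c, gen$label)
  mus <- sort(vapply(by_class, mean, numeric(1)))
  sd_max <- max(vapply(by_class, sd, numeric(1)))
  expect_true(all(diff(mus) >= 4 * sd_max))
  plan <- make_stratified_folds(gen$label, k = 5, seed = 42)
  for (kind in model_kinds()) {
    r <- cross_validate(kind, gen[, indicator_features()], gen$label,
                        plan, scaler = if (kind == "RF") "none" else
                          "standard", seed = 42)
    expect_gte(r$mean_accuracy, 0.95)
  }
})

test_that("adjacent-class overlap concentrates confusion on that pair", {
  ind <- make_indicator_table(n_per_class = 12, seed = 36)
  # erase the O/W mean contrast (keep within-class noise) so those two
  # classes become indistinguishable while the others stay separable
  for (f in indicator_features()) {
    o <- ind$label == "O"; w <- ind$label == "W"
    mu <- mean(ind[[f]][o | w])
    ind[[f]][o] <- ind[[f]][o] - mean(ind[[f]][o]) + mu
    ind[[f]][w] <- ind[[f]][w] - mean(ind[[f]][w]) + mu
  }
  plan <- make_stratified_folds(ind$label, k = 5, seed = 42)
  r <- cross_validate("KNN", ind[, indicator_features()], ind$label, plan)
  cm <- r$confusion$counts
  off <- cm; diag(off) <- 0
  ow_err <- off["O", "W"] + off["W", "O"]
  expect_gte(ow_err / max(1, sum(off)), 0.8)
})

test_that("fitting is deterministic under a fixed seed", {
  ind <- make_indicator_table(n_per_class = 8, seed = 37)
  for (kind in c("RF", "MLP")) {
    m1 <- fit_stage_model(kind, ind, indicator_features(), seed = 9)
    m2 <- fit_stage_model(kind, ind, indicator_features(), seed = 9)
    expect_equal(predict(m1, ind)$proba, predict(m2, ind)$proba)
  }
})

test_that("stage models round-trip through their binary + sidecar", {
  ind <- make_indicator_table(n_per_class = 8, seed = 38)
  feats <- c("leaf_temp_c", "cwsi", "ndvi", "spad")
  m <- fit_stage_model("KNN", ind, feats, seed = 42, stage = "early")
  path <- tempfile(fileext = ".rds")
  save_stage_model(m, path)
  m2 <- load_stage_model(path)
  expect_equal(predict(m2, ind)$proba, predict(m, ind)$proba)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(side$kind, "KNN")
  expect_equal(side$features, feats)
  expect_equal(stage_months()[["June"]], "early")
})
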