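# Stratified evaluation protocol: seeded stratified k-fold plans, a
# stratified 80/20 split, and leakage-safe cross-validation in which any
# feature scaling is fitted on the training subset of each fold only.

#' Stratified k-fold plan
#'
#' Builds a deterministic stratified fold assignment: within each class,
#' indices are shuffled under the seed and dealt round-robin (with a
#' random per-class rotation) so that each fold's class histogram deviates
#' from the global distribution by at most one record per class. One plan
#' is meant to be reused across all models being compared.
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @param seed RNG seed (default 42).
#' @return A `fold_plan`: list with `k`, `seed`, `assignments` (fold index
#'   per record), `stratified = TRUE`.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 42L) {
  labels <- as.character(labels)
  if (k < 2L) stop_invalid("k must be >= 2 (got ", k, ")")
  tab <- table(labels)
  if (any(tab < k)) {
    stop_invalid("class(es) smaller than k=", k, ": ",
                 paste(names(tab)[tab < k], collapse = ", "),
                 class = "cwsifusion_stratification_error")
  }
  assignments <- integer(length(labels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    folds <- ((seq_along(idx) - 1L + start - 1L) %% k) + 1L
    assignments[idx] <- folds
  }
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments, stratified = TRUE),
            class = "fold_plan")
}

# Save/restore global RNG state so seeded utilities do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Stratified train/test split
#'
#' @param labels Class label vector.
#' @param test_frac Held-out fraction (default 0.2).
#' @param seed RNG seed (default 42).
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_frac = 0.2, seed = 42L) {
  labels <- as.character(labels)
  check_range(test_frac, 0, 1, "test_frac")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_frac))
    test <- c(test, idx[sample.int(length(idx), n_test)])
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Per-class sample counts for a ratio design
#'
#' Expands a class ratio (for the five-level stress design the published
#' ratio is 1:1:2:1:1 with the optimal class doubled) into per-class
#' counts given a unit count.
#'
#' @param n_unit Samples per ratio unit.
#' @param ratios Named integer ratios per class.
#' @return Named integer vector of counts.
#' @export
design_counts <- function(n_unit = 50L,
                          ratios = c(SD = 1L, D = 1L, O = 2L, W = 1L,
                                     SW = 1L)) {
  stats::setNames(as.integer(round(n_unit * ratios)), names(ratios))
}

#' Write a fold plan as CSV
#'
#' @param plan A `fold_plan`.
#' @param path Output path; columns `record_id`, `fold`.
#' @export
write_fold_plan <- function(plan, path) {
  utils::write.csv(data.frame(record_id = seq_along(plan$assignments),
                              fold = plan$assignments),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- scaling ----------------------------------------------------------

fit_scaler <- function(x, kind = c("standard", "none")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (kind == "none") {
    return(list(kind = "none", center = rep(0, ncol(x)),
                scale = rep(1, ncol(x))))
  }
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  list(kind = "standard", center = colMeans(x), scale = s)
}

apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Leakage-safe cross-validation
#'
#' Evaluates a classifier specification over a shared [make_stratified_folds()]
#' plan. In each fold the feature scaler is fitted on the training subset
#' only and then applied to the validation subset, so no validation
#' statistic leaks into preprocessing.
#'
#' @param spec Classifier spec: a `model_kind` string (`"LR"`, `"RF"`,
#'   `"KNN"`, `"MLP"`, `"SVM"`, or `"constant"` for a chance-level
#'   baseline) or a list with elements `kind` and optional `params`.
#' @param features Numeric feature matrix / data frame.
#' @param labels Class labels.
#' @param plan A `fold_plan` covering all records.
#' @param scaler `"standard"` or `"none"`.
#' @param seed Seed forwarded to stochastic learners.
#' @return A `cv_report`: per-fold accuracy/macro-F1, their mean and sd,
#'   the pooled confusion matrix, and the per-fold scaler statistics.
#' @export
cross_validate <- function(spec, features, labels, plan,
                           scaler = c("standard", "none"), seed = 42L) {
  scaler <- match.arg(scaler)
  if (is.character(spec)) spec <- list(kind = spec)
  stopifnot(inherits(plan, "fold_plan"))
  labels <- as.character(labels)
  x <- as.matrix(features)
  if (length(labels) != nrow(x) ||
      length(plan$assignments) != nrow(x)) {
    stop_invalid("plan/labels do not cover the feature rows")
  }
  classes <- sort(unique(labels))
  fold_acc <- fold_f1 <- numeric(plan$k)
  scaler_stats <- vector("list", plan$k)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (f in seq_len(plan$k)) {
    tr <- plan$assignments != f
    sc <- fit_scaler(x[tr, , drop = FALSE], scaler)
    scaler_stats[[f]] <- sc
    x_tr <- apply_scaler(sc, x[tr, , drop = FALSE])
    x_va <- apply_scaler(sc, x[!tr, , drop = FALSE])
    fit <- fit_classifier(spec$kind, x_tr, labels[tr], seed = seed,
                          params = spec$params)
    pred <- predict_classifier(fit, x_va)$label
    cm <- confusion_from_labels(labels[!tr], pred, labels = classes)
    rep_f <- suppressWarnings(metrics_from_confusion(cm))
    fold_acc[f] <- rep_f$accuracy
    fold_f1[f] <- rep_f$macro[["f1"]]
    pooled <- pooled + cm$counts
  }
  structure(list(
    kind = spec$kind,
    fold_accuracy = fold_acc, fold_macro_f1 = fold_f1,
    mean_accuracy = mean(fold_acc), sd_accuracy = stats::sd(fold_acc),
    mean_macro_f1 = mean(fold_f1), sd_macro_f1 = stats::sd(fold_f1),
    confusion = confusion_matrix(pooled, labels = classes),
    scaler_stats = scaler_stats
  ), class = "cv_report")
}
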