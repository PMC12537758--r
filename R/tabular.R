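# Growth-stage tabular classifiers over plant indicators.
#
# Per-plant growth indicators (stem length, NDVI, chlorophyll
# fluorescence, SPAD) joined with leaf temperature and CWSI form the
# feature space. A seeded random forest ranks feature importance per
# growth stage; the top four features feed five classifier families (LR,
# RF, KNN, MLP, SVM), each trained separately per stage.

#' Indicator feature names
#'
#' Canonical order of the tabular feature space; also the tie-break order
#' for [select_top_k()].
#'
#' @return Character vector of column names.
#' @export
indicator_features <- function() {
  c("leaf_temp_c", "cwsi", "stem_length", "cf", "ndvi", "spad")
}

#' Growth stages
#'
#' Stage codes with their calendar-month counterparts on the original
#' trial (June = early growth, July = tuber bulking, August = late
#' growth).
#'
#' @return Named character vector mapping month name to stage code.
#' @export
stage_months <- function() {
  c(June = "early", July = "tuber", August = "late")
}

#' Random-forest feature importance ranking
#'
#' Fits a seeded random forest of the stress label on the indicator
#' features and reports normalized importance scores (summing to one).
#' Impurity-based importance (mean decrease in Gini) is the default;
#' permutation importance (mean decrease in accuracy) is available.
#'
#' @param records Data frame with the [indicator_features()] columns and a
#'   `label` column (two or more classes must be present).
#' @param features Feature columns to rank.
#' @param method `"impurity"` or `"permutation"`.
#' @param seed RNG seed for the forest.
#' @param ntree Number of trees.
#' @param stage Optional stage tag carried in the result.
#' @return An `importance_ranking`: list with named `scores` (sum 1),
#'   `stage`, `method`.
#' @export
rank_features <- function(records, features = indicator_features(),
                          method = c("impurity", "permutation"),
                          seed = 42L, ntree = 500L, stage = NULL) {
  method <- match.arg(method)
  check_columns(records, c(features, "label"))
  if (nrow(records) < 2L) stop_invalid("need at least 2 records")
  y <- factor(as.character(records$label))
  if (nlevels(y) < 2L) {
    stop_invalid("feature ranking needs at least 2 classes (got ",
                 nlevels(y), ")")
  }
  x <- as.matrix(records[, features, drop = FALSE])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree,
                                   importance = (method == "permutation"))
  imp <- randomForest::importance(rf)
  col <- if (method == "impurity") "MeanDecreaseGini" else
    "MeanDecreaseAccuracy"
  scores <- pmax(imp[features, col], 0)
  scores <- scores / sum(scores)
  structure(list(scores = scores, stage = stage, method = method),
            class = "importance_ranking")
}

#' Manually constructed importance ranking
#'
#' Wraps externally obtained importance scores (e.g. a published
#' calibration table) so they can drive [select_top_k()].
#'
#' @param scores Named numeric scores; normalized to sum 1.
#' @param stage Optional stage tag.
#' @return An `importance_ranking`.
#' @export
importance_ranking <- function(scores, stage = NULL) {
  if (is.null(names(scores))) stop_invalid("scores must be named")
  check_finite(scores, "scores")
  if (any(scores < 0)) stop_invalid("scores must be >= 0")
  structure(list(scores = scores / sum(scores), stage = stage,
                 method = "external"),
            class = "importance_ranking")
}

#' Select the top-k features from a ranking
#'
#' Features ordered by descending score; ties broken by position in the
#' ranking's own feature order (stable sort), so equal scores keep their
#' canonical sequence.
#'
#' @param ranking An `importance_ranking`.
#' @param k Number of features to keep (default 4).
#' @return Character vector of `k` feature names, highest score first.
#' @export
select_top_k <- function(ranking, k = 4L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (k > length(ranking$scores)) {
    stop_invalid("k = ", k, " exceeds the ", length(ranking$scores),
                 " ranked features")
  }
  ord <- order(-ranking$scores, seq_along(ranking$scores))
  names(ranking$scores)[ord][seq_len(k)]
}

#' Fit a growth-stage classifier
#'
#' Pipeline = feature scaler fitted on the training data, then the chosen
#' classifier family. Standardization is applied for the distance- and
#' gradient-based families (LR, KNN, MLP, SVM); forests are scale
#' invariant and skip it. The selected feature set is frozen at fit time.
#'
#' @param kind One of `"LR"`, `"RF"`, `"KNN"`, `"MLP"`, `"SVM"`.
#' @param records Training data frame with feature columns and `label`.
#' @param selected_features Feature columns the model uses (typically from
#'   [select_top_k()]).
#' @param seed RNG seed for stochastic learners.
#' @param stage Optional stage tag.
#' @param params Optional hyperparameter overrides (see
#'   `default_hyperparameters`).
#' @return A `stage_model`.
#' @export
fit_stage_model <- function(kind, records, selected_features,
                            seed = 42L, stage = NULL, params = NULL) {
  check_columns(records, c(selected_features, "label"))
  if (nrow(records) == 0L) stop_invalid("no training records")
  x <- as.matrix(records[, selected_features, drop = FALSE])
  scaler <- fit_scaler(x, if (kind == "RF") "none" else "standard")
  clf <- fit_classifier(kind, apply_scaler(scaler, x), records$label,
                        seed = seed, params = params)
  structure(list(kind = kind, stage = stage,
                 selected_features = selected_features,
                 scaler = scaler, classifier = clf, seed = seed),
            class = "stage_model")
}

#' Predict from a growth-stage classifier
#'
#' @param object A `stage_model`.
#' @param newdata Data frame (or matrix) holding the model's features.
#' @param ... Unused.
#' @return List with `proba` (rows sum to 1, columns in class order) and
#'   `label`.
#' @export
predict.stage_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    check_columns(newdata, object$selected_features)
    newdata <- as.matrix(newdata[, object$selected_features, drop = FALSE])
  }
  predict_classifier(object$classifier, apply_scaler(object$scaler, newdata))
}

#' Evaluate all classifier families on one fold plan
#'
#' Runs [cross_validate()] for every model family on identical folds so
#' the comparison is paired, and returns per-family reports plus pooled
#' confusion matrices.
#'
#' @param records Data frame with feature columns and `label`.
#' @param plan A `fold_plan` over `records`.
#' @param features Feature columns to use.
#' @param kinds Model families to evaluate.
#' @param seed RNG seed forwarded to stochastic learners.
#' @return Named list of `cv_report` objects, one per family.
#' @export
evaluate_stage_models <- function(records, plan,
                                  features = indicator_features(),
                                  kinds = model_kinds(), seed = 42L) {
  if (nrow(records) == 0L) stop_invalid("no records to evaluate")
  check_columns(records, c(features, "label"))
  x <- records[, features, drop = FALSE]
  out <- lapply(kinds, function(kind) {
    cross_validate(kind, x, records$label, plan,
                   scaler = if (kind == "RF") "none" else "standard",
                   seed = seed)
  })
  stats::setNames(out, kinds)
}

#' Save / load a fitted stage model
#'
#' The fitted state is written as a versioned binary with a JSON sidecar
#' (`<path>.json`) recording kind, stage, features, seed.
#'
#' @param model A `stage_model`.
#' @param path Output path for the binary.
#' @export
save_stage_model <- function(model, path) {
  stopifnot(inherits(model, "stage_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  jsonlite::write_json(list(format_version = 1L, kind = model$kind,
                            stage = model$stage,
                            features = model$selected_features,
                            seed = model$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_stage_model
#' @export
load_stage_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop_invalid("unsupported stage model format: ", obj$format_version)
  }
  obj$model
}
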