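# Classification metrics from multiclass confusion matrices.
#
# Per-class precision, recall and F1 are computed one-vs-rest from the
# K x K matrix (rows = truth, columns = prediction); overall accuracy is
# trace/total, to which the binary (TP+TN)/(TP+TN+FP+FN) form reduces in
# the one-vs-rest aggregate.

#' Confusion matrix container
#'
#' @param counts Square matrix of non-negative integer counts; rows are
#'   true classes, columns predicted classes.
#' @param labels Optional class labels (defaults to dimnames or indices).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop_invalid("counts must be square")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  labels <- labels %||% rownames(counts) %||% as.character(seq_len(nrow(counts)))
  dimnames(counts) <- list(truth = labels, predicted = labels)
  structure(list(counts = counts, labels = labels),
            class = "confusion_matrix")
}

#' Tabulate a confusion matrix from labels
#'
#' @param truth,predicted Vectors (coerced to factors over `labels`).
#' @param labels Class order.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, predicted,
                                  labels = sort(unique(c(as.character(truth),
                                                         as.character(predicted))))) {
  t_f <- factor(as.character(truth), levels = labels)
  p_f <- factor(as.character(predicted), levels = labels)
  confusion_matrix(unclass(table(t_f, p_f)), labels = labels)
}

#' Metric report from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return A `metric_report`: list with `per_class` (data frame of
#'   precision, recall, f1, support), `accuracy`, `macro` and `weighted`
#'   aggregates. Classes with zero predicted (or true) positives get
#'   precision (recall) 0 with a warning.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop_invalid("confusion matrix is empty")
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  zero_pred <- (tp + fp) == 0
  zero_true <- (tp + fn) == 0
  if (any(zero_pred)) {
    warning("class(es) with zero predicted positives; precision set to 0: ",
            paste(cm$labels[zero_pred], collapse = ", "))
  }
  if (any(zero_true)) {
    warning("class(es) with zero true members; recall set to 0: ",
            paste(cm$labels[zero_true], collapse = ", "))
  }
  precision <- ifelse(zero_pred, 0, tp / (tp + fp))
  recall <- ifelse(zero_true, 0, tp / (tp + fn))
  pr_sum <- precision + recall
  f1 <- ifelse(pr_sum == 0, 0, 2 * precision * recall / pr_sum)
  support <- rowSums(counts)
  per_class <- data.frame(class = cm$labels, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL)
  wts <- support / total
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(wts * precision),
                 recall = sum(wts * recall), f1 = sum(wts * f1))
  ), class = "metric_report")
}

#' Serialize metric artifacts
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(list(
    per_class = report$per_class, accuracy = report$accuracy,
    macro = as.list(report$macro), weighted = as.list(report$weighted)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_report
#' @param cm A [confusion_matrix()] to write as CSV.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(cm$counts, path)
  invisible(path)
}
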