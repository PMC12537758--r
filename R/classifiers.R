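# Shared classifier backends for the growth-stage models and the
# cross-validation protocol. Each backend fits on an (already scaled)
# numeric matrix and predicts a full class-probability matrix; defaults
# are the common library defaults, kept deterministic through seeds.

model_kinds <- function() c("LR", "RF", "KNN", "MLP", "SVM")

default_hyperparameters <- function(kind) {
  switch(kind,
    LR = list(maxit = 500),
    RF = list(ntree = 500),
    KNN = list(k = 5),
    MLP = list(size = 64, decay = 1e-3, maxit = 500),
    SVM = list(cost = 1, kernel = "radial"),
    constant = list(),
    stop_invalid("unknown model kind: ", kind,
                 class = "cwsifusion_config_error")
  )
}

fit_classifier <- function(kind, x, y, seed = 42L, params = NULL) {
  if (!kind %in% c(model_kinds(), "constant")) {
    stop_invalid("unknown model kind: ", kind,
                 class = "cwsifusion_config_error")
  }
  hp <- utils::modifyList(default_hyperparameters(kind),
                          params %||% list())
  x <- as.matrix(x)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- switch(kind,
    LR = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     maxit = hp$maxit, MaxNWts = 100000)
    },
    RF = randomForest::randomForest(x, y, ntree = hp$ntree),
    KNN = caret::knn3(x, y, k = hp$k),
    MLP = nnet::nnet(x, nnet::class.ind(y), size = hp$size,
                     softmax = TRUE, decay = hp$decay, maxit = hp$maxit,
                     MaxNWts = 100000, trace = FALSE),
    SVM = e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE),
    constant = {
      tab <- table(y)
      list(label = names(tab)[which.max(tab)])
    }
  )
  structure(list(kind = kind, fit = fit, levels = levels(y),
                 features = colnames(x), hyperparameters = hp,
                 seed = seed),
            class = "cwsifusion_classifier")
}

predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "cwsifusion_classifier"))
  x <- as.matrix(x)
  colnames(x) <- model$features
  lv <- model$levels
  proba <- switch(model$kind,
    LR = {
      df <- data.frame(x, check.names = FALSE)
      p <- predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(p))) {   # binary case returns P(second level)
        p <- cbind(1 - p, p)
        colnames(p) <- lv
      }
      p
    },
    RF = predict(model$fit, x, type = "prob"),
    KNN = predict(model$fit, x, type = "prob"),
    MLP = {
      p <- predict(model$fit, x)
      colnames(p) <- lv
      p
    },
    SVM = {
      pr <- predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    constant = {
      p <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
      p[, model$label] <- 1
      p
    }
  )
  proba <- as.matrix(proba)[, lv, drop = FALSE]  # canonical column order
  if (nrow(proba) != nrow(x)) proba <- matrix(proba, nrow = nrow(x))
  list(proba = proba, label = lv[max.col(proba, ties.method = "first")])
}
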