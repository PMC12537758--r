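# Training loop for the fusion classifier: Adam on sparse categorical
# cross-entropy, mini-batches, validation-loss early stopping with
# best-weight restoration, and the thermal channel mask computed on a
# reference batch after a one-epoch warm-up and then frozen.

sparse_ce <- function(proba, y_idx) {
  eps <- 1e-12
  -mean(log(pmax(proba[cbind(seq_along(y_idx), y_idx)], eps)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gn <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gn
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gn^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

label_indices <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) {
    stop_invalid("labels outside the model's classes: ",
                 paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Train the fusion classifier
#'
#' Optimizes the model with Adam on sparse categorical cross-entropy in
#' mini-batches. Unless a validation split is disabled, an internal
#' stratified 80/20 split monitors validation loss; training stops early
#' once the loss has not improved by `min_delta` for
#' `early_stop_patience` epochs and the best-validation-loss weights are
#' restored. The thermal channel mask is computed on the first training
#' batch after a one-epoch warm-up and frozen for the rest of training.
#'
#' @param model A [build_fusion_model()] object.
#' @param rgb Batch array `N x side x side x 3` in `[0, 1]`.
#' @param thermal Batch array `N x side x side x 1` in `[0, 1]`.
#' @param labels Class labels (must be in `model$classes`).
#' @param validation `"split"` (stratified 80/20 on the model seed) or
#'   `"none"` (train on everything; no early stopping).
#' @param subset Optional integer indices: train only on these rows of
#'   the batch arrays (avoids copying large arrays to subset them).
#' @param stop_at_train_accuracy Optional: stop once training accuracy
#'   reaches this value (useful for capacity/overfit checks with
#'   `validation = "none"`).
#' @param max_epochs Optional override of the configured epoch cap.
#' @param verbose Print per-epoch losses?
#' @return The trained `fusion_model`, with `history` (data frame of
#'   epoch, train/validation loss and accuracy) and `mask` attached.
#' @export
train_fusion <- function(model, rgb, thermal, labels,
                         validation = c("split", "none"),
                         subset = NULL, stop_at_train_accuracy = NULL,
                         max_epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"))
  validation <- match.arg(validation)
  cfg <- model$config
  rgb <- as_batch(rgb, cfg$input_side, 3L)
  thermal <- as_batch(thermal, cfg$input_side, 1L)
  n <- dim(rgb)[1]
  if (dim(thermal)[1] != n || length(labels) != n) {
    stop_invalid("rgb, thermal and labels must have matching lengths")
  }
  y <- label_indices(labels, model$classes)
  max_epochs <- max_epochs %||% cfg$max_epochs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  idx_all <- as.integer(subset %||% seq_len(n))
  if (validation == "split") {
    sp <- stratified_split(model$classes[y[idx_all]], 0.2,
                           seed = cfg$seed)
    tr <- idx_all[sp$train]; va <- idx_all[sp$test]
  } else {
    tr <- idx_all; va <- integer(0)
  }
  ws_train <- fusion_workspaces()
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, mask = model$mask,
               epoch = 0L)
  wait <- 0L
  hist <- data.frame()

  take <- function(x, i) x[i, , , , drop = FALSE]
  for (epoch in seq_len(max_epochs)) {
    ord <- tr[sample.int(length(tr))]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tr_loss <- 0; tr_hits <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      cc <- fusion_forward(model, take(rgb, b), take(thermal, b),
                           cache = TRUE, ws = ws_train)
      yb <- y[b]
      onehot <- matrix(0, length(b), cfg$n_classes)
      onehot[cbind(seq_along(b), yb)] <- 1
      dlogits <- (cc$proba - onehot) / length(b)
      bw <- fusion_backward(model, cc, dlogits)
      upd <- adam_step(model$params, bw$grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + sparse_ce(cc$proba, yb) * length(b)
      tr_hits <- tr_hits + sum(max.col(cc$proba) == yb)
      if (epoch == 1L && bi == 1L && is.null(model$mask)) {
        # warm-up reference batch activations; mask frozen below after
        # the first full epoch
        ref_batch <- b
      }
    }
    if (epoch == 1L && is.null(model$mask)) {
      cc_ref <- fusion_forward(model, take(rgb, ref_batch),
                               take(thermal, ref_batch), cache = TRUE,
                               ws = ws_train, want_a3 = TRUE)
      model$mask <- compute_channel_mask(cc_ref$bt$a3,
                                         cfg$mask_threshold)
    }
    row <- data.frame(epoch = epoch,
                      train_loss = tr_loss / length(tr),
                      train_accuracy = tr_hits / length(tr),
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (length(va)) {
      # validate in batch-sized chunks, reusing the training workspace
      # (no backward is pending at this point)
      v_loss <- 0; v_hits <- 0
      for (vb in split(va, ceiling(seq_along(va) / cfg$batch_size))) {
        vp <- fusion_forward(model, take(rgb, vb), take(thermal, vb),
                             ws = ws_train)
        v_loss <- v_loss + sparse_ce(vp$proba, y[vb]) * length(vb)
        v_hits <- v_hits + sum(max.col(vp$proba) == y[vb])
      }
      row$val_loss <- v_loss / length(va)
      row$val_accuracy <- v_hits / length(va)
      if (row$val_loss < best$loss - cfg$min_delta) {
        best <- list(loss = row$val_loss, params = model$params,
                     mask = model$mask, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, row)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, row$train_loss, row$train_accuracy,
                      row$val_loss %||% NA, row$val_accuracy %||% NA))
    }
    if (length(va) && wait >= cfg$early_stop_patience) break
    if (!is.null(stop_at_train_accuracy) &&
        row$train_accuracy >= stop_at_train_accuracy) break
  }
  if (length(va) && is.finite(best$loss)) {
    model$params <- best$params
    model$mask <- best$mask
  }
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- if (length(va)) best$epoch else nrow(hist)
  model
}

#' Save / load a fusion model
#'
#' Weights and configuration are written as a versioned binary with a
#' JSON sidecar (`<path>.json`) describing the architecture, seed and
#' channel mask.
#'
#' @param model A `fusion_model`.
#' @param path Output path for the binary.
#' @export
save_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  jsonlite::write_json(list(
    format_version = 1L, config = unclass(model$config),
    n_parameters = model$n_parameters, trained = model$trained,
    mask_keep = model$mask$keep %||% NULL
  ), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fusion_model
#' @export
load_fusion_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop_invalid("unsupported fusion model format: ", obj$format_version)
  }
  obj$model
}
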