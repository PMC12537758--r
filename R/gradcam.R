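# Grad-CAM explanations for the fusion classifier.
#
# For a chosen branch and target class, the gradient of the target-class
# logit with respect to the branch's final convolutional feature maps is
# averaged over space to give one weight per channel; the weighted sum of
# the activation maps, rectified and normalized to [0, 1], localizes the
# image evidence for that class and is upsampled to the input size.

#' Grad-CAM heatmap
#'
#' @param model A trained [build_fusion_model()] object.
#' @param rgb Preprocessed RGB input (`side x side x 3` in `[0, 1]`).
#' @param thermal Preprocessed thermal input (`side x side x 1`).
#' @param branch `"rgb"` or `"thermal"`: whose evidence to visualize.
#' @param target_class Class code (in `model$classes`) or index; defaults
#'   to the predicted class.
#' @return A `heatmap` object: list with `values` (input-side square
#'   matrix in `[0, 1]`, maximum 1 unless degenerate), `branch`,
#'   `target_class`, `degenerate` flag.
#' @export
grad_cam <- function(model, rgb, thermal, branch = c("rgb", "thermal"),
                     target_class = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  branch <- match.arg(branch)
  side <- model$config$input_side
  rgb <- as_batch(rgb, side, 3L)
  thermal <- as_batch(thermal, side, 1L)
  if (dim(rgb)[1] != 1L) stop_invalid("grad_cam takes a single sample")
  cc <- fusion_forward(model, rgb, thermal, cache = TRUE,
                       want_a3 = TRUE)
  if (is.null(target_class)) {
    target_idx <- which.max(cc$proba[1, ])
  } else if (is.character(target_class)) {
    target_idx <- match(target_class, model$classes)
    if (is.na(target_idx)) {
      stop_invalid("unknown target class: ", target_class)
    }
  } else {
    target_idx <- as.integer(target_class)
  }
  # gradient of the target logit (pre-softmax score)
  dlogits <- matrix(0, 1, model$config$n_classes)
  dlogits[1, target_idx] <- 1
  bw <- fusion_backward(model, cc, dlogits, want_da3 = TRUE)
  acts <- if (branch == "rgb") cc$br$a3 else cc$bt$a3
  grads <- if (branch == "rgb") bw$da3_rgb else bw$da3_th
  cam <- cam_from_activations(acts[1, , , , drop = TRUE],
                              grads[1, , , , drop = TRUE])
  values <- if (attr(cam, "degenerate")) {
    matrix(0, side, side)
  } else {
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(t(cam)),
                                             w = side, h = side))
    up <- pmin(pmax(t(up), 0), 1)
    if (max(up) > 0) up / max(up) else up
  }
  structure(list(values = values, branch = branch,
                 target_class = model$classes[target_idx],
                 degenerate = attr(cam, "degenerate")),
            class = "heatmap")
}

#' Raw class-activation map from activations and gradients
#'
#' The core Grad-CAM arithmetic, exposed so it can be verified against
#' closed-form cases: channel weights are the spatial means of the
#' gradients, the map is the ReLU of the weighted activation sum, scaled
#' so its maximum is 1 (all-zero maps are flagged degenerate).
#'
#' @param activations `H x W x C` feature activations.
#' @param gradients `H x W x C` gradients of the target score w.r.t. the
#'   activations.
#' @return `H x W` matrix in `[0, 1]` with attribute `degenerate`.
#' @export
cam_from_activations <- function(activations, gradients) {
  d <- dim(activations)
  if (!identical(d, dim(gradients)) || length(d) != 3L) {
    stop_invalid("activations and gradients must be matching H x W x C")
  }
  w <- colMeans(matrix(gradients, d[1] * d[2], d[3]))
  cam <- matrix(matrix(activations, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  attr(cam, "degenerate") <- mx <= 0
  cam
}

#' Write a heatmap to disk
#'
#' Writes the raw map as a CSV grid and, optionally, a PNG overlay on the
#' source image (heat in red, image as luminance backdrop).
#'
#' @param hm A `heatmap`.
#' @param path Output CSV path.
#' @param overlay_png Optional PNG path for an overlay.
#' @param image Optional [rgb_image()] the overlay is drawn over.
#' @export
write_heatmap <- function(hm, path, overlay_png = NULL, image = NULL) {
  utils::write.table(hm$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(overlay_png)) {
    side <- nrow(hm$values)
    base <- if (!is.null(image)) {
      px <- preprocess_for_model(image, side = side)
      luminance255(px * 255) / 255
    } else {
      matrix(0, side, side)
    }
    ov <- array(0, c(side, side, 3))
    ov[, , 1] <- pmin(1, 0.5 * base + hm$values)
    ov[, , 2] <- 0.5 * base
    ov[, , 3] <- 0.5 * base
    write_rgb_image(rgb_image(ov, range = "unit"), overlay_png)
  }
  invisible(path)
}
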