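# Dual-branch CNN + transformer fusion classifier.
#
# Two small CNNs extract local features from the RGB and thermal inputs
# separately (three 3x3 conv blocks with ReLU and 2x2 max pooling). The
# thermal branch's final feature maps pass through a channel mask that
# keeps only channels whose mean activation exceeds a threshold. Each
# branch is reduced by global average pooling, the two vectors are
# concatenated, and the fused vector -- reshaped into a short token
# sequence -- is processed by one transformer encoder block
# (multi-head self-attention + feed-forward, post-layer-norm) before a
# dense softmax head predicts the stress class. The network is authored
# in-package (R orchestration over BLAS-backed C++ conv/pool kernels) and
# its gradients are verified against finite differences in the test
# suite.

#' Fusion model configuration
#'
#' Defaults follow the published training setup (128 px inputs, Adam at
#' 0.001, sparse categorical cross-entropy, batch 64, up to 100 epochs
#' with early-stopping patience 10 on validation loss, thermal channel
#' mask threshold 0.1) with branch and transformer widths chosen to land
#' near 2.2e5 trainable parameters.
#'
#' @param input_side Input spatial side, px.
#' @param n_classes 3 or 5 output classes.
#' @param conv_filters Filter counts of the three conv blocks per branch.
#' @param n_tokens Number of tokens the fused vector is reshaped into.
#' @param d_model Transformer model width.
#' @param n_heads Attention heads (must divide `d_model`).
#' @param ff_dim Feed-forward hidden width.
#' @param dense_units Width of the dense layer before the softmax head.
#' @param mask_threshold Thermal channel-mask activation threshold.
#' @param learning_rate,batch_size,max_epochs,early_stop_patience,min_delta
#'   Training hyperparameters (Adam; patience on validation loss).
#' @param seed RNG seed for weight initialization and shuffling.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(input_side = 128L, n_classes = 3L,
                          conv_filters = c(16L, 32L, 64L),
                          n_tokens = 8L, d_model = 64L, n_heads = 4L,
                          ff_dim = 128L, dense_units = 256L,
                          mask_threshold = 0.1, learning_rate = 0.001,
                          batch_size = 64L, max_epochs = 100L,
                          early_stop_patience = 10L, min_delta = 1e-3,
                          seed = 42L) {
  if (!n_classes %in% c(3L, 5L)) {
    stop_invalid("n_classes must be 3 or 5 (got ", n_classes, ")",
                 class = "cwsifusion_config_error")
  }
  if (length(conv_filters) != 3L || any(conv_filters < 1)) {
    stop_invalid("conv_filters must be three positive counts",
                 class = "cwsifusion_config_error")
  }
  if (input_side %% 8L != 0L) {
    stop_invalid("input_side must be divisible by 8 (three 2x2 poolings)",
                 class = "cwsifusion_config_error")
  }
  if (d_model %% n_heads != 0L) {
    stop_invalid("n_heads must divide d_model",
                 class = "cwsifusion_config_error")
  }
  fused_len <- 2L * conv_filters[3]
  if (fused_len %% n_tokens != 0L) {
    stop_invalid("n_tokens must divide the fused vector length (",
                 fused_len, ")", class = "cwsifusion_config_error")
  }
  for (nm in c("mask_threshold", "learning_rate", "min_delta")) {
    check_finite(get(nm), nm)
  }
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1 ||
      early_stop_patience < 1) {
    stop_invalid("training hyperparameters must be positive",
                 class = "cwsifusion_config_error")
  }
  structure(list(
    input_side = as.integer(input_side), n_classes = as.integer(n_classes),
    rgb_channels = 3L, thermal_channels = 1L,
    conv_filters = as.integer(conv_filters),
    n_tokens = as.integer(n_tokens), d_model = as.integer(d_model),
    n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
    dense_units = as.integer(dense_units),
    token_dim = as.integer(fused_len / n_tokens),
    mask_threshold = mask_threshold, optimizer = "adam",
    loss = "sparse_categorical_crossentropy",
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    min_delta = min_delta, seed = as.integer(seed)
  ), class = "fusion_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

xavier_init <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_fusion_params <- function(cfg) {
  f <- cfg$conv_filters
  p <- list()
  ins <- c(cfg$rgb_channels, f[1], f[2])
  tns <- c(cfg$thermal_channels, f[1], f[2])
  for (l in 1:3) {
    p[[paste0("rgb_w", l)]] <- he_init(c(3, 3, ins[l], f[l]), 9 * ins[l])
    p[[paste0("rgb_b", l)]] <- numeric(f[l])
    p[[paste0("th_w", l)]] <- he_init(c(3, 3, tns[l], f[l]), 9 * tns[l])
    p[[paste0("th_b", l)]] <- numeric(f[l])
  }
  d <- cfg$d_model
  p$embed_w <- xavier_init(cfg$token_dim, d)
  p$embed_b <- numeric(d)
  for (nm in c("wq", "wk", "wv", "wo")) {
    p[[nm]] <- xavier_init(d, d)
    p[[paste0("b", substr(nm, 2, 2))]] <- numeric(d)
  }
  p$ln1_g <- rep(1, d); p$ln1_b <- numeric(d)
  p$ff_w1 <- xavier_init(d, cfg$ff_dim); p$ff_b1 <- numeric(cfg$ff_dim)
  p$ff_w2 <- xavier_init(cfg$ff_dim, d); p$ff_b2 <- numeric(d)
  p$ln2_g <- rep(1, d); p$ln2_b <- numeric(d)
  flat <- cfg$n_tokens * d
  p$dense_w <- he_init(c(flat, cfg$dense_units), flat)
  p$dense_b <- numeric(cfg$dense_units)
  # small-scale head init: the classifier starts near the uniform
  # softmax, so the initial loss sits at ~ln(K) regardless of input
  p$head_w <- xavier_init(cfg$dense_units, cfg$n_classes) * 0.1
  p$head_b <- numeric(cfg$n_classes)
  p
}

#' Build a fusion model
#'
#' Initializes the dual-branch CNN + transformer classifier with seeded
#' weights and reports the trainable parameter count.
#'
#' @param config A [fusion_config()].
#' @return An object of class `fusion_model`: list with `config`,
#'   `params`, `n_parameters`, `mask` (NULL until computed), `classes`
#'   and `trained` flag.
#' @export
build_fusion_model <- function(config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- init_fusion_params(config)
  classes <- if (config$n_classes == 3L) stress_levels3() else
    stress_levels5()
  structure(list(
    config = config, params = params,
    n_parameters = sum(vapply(params, length, numeric(1))),
    mask = NULL, mask_info = NULL, classes = classes, trained = FALSE
  ), class = "fusion_model")
}

#' Thermal channel mask from feature activations
#'
#' Importance of each thermal feature channel is the mean of its
#' activation over the batch and spatial axes; channels whose mean is
#' strictly greater than the threshold are kept, and the resulting mask
#' is applied uniformly to all thermal features. If no channel passes,
#' the single highest-mean channel is kept and the mask is flagged
#' degenerate (so the branch never goes fully dead).
#'
#' @param feature_maps Batch x H x W x C array of thermal feature
#'   activations.
#' @param threshold Strict activation threshold (default 0.1).
#' @return A `channel_mask`: list with logical `keep`, `channel_means`,
#'   `threshold` and `degenerate` flag.
#' @export
compute_channel_mask <- function(feature_maps, threshold = 0.1) {
  d <- dim(feature_maps)
  if (length(d) != 4L) stop_invalid("feature_maps must be N x H x W x C")
  means <- colMeans(matrix(feature_maps, prod(d[1:3]), d[4]))
  keep <- means > threshold
  degenerate <- !any(keep)
  if (degenerate) keep[which.max(means)] <- TRUE
  structure(list(keep = keep, channel_means = means,
                 threshold = threshold, degenerate = degenerate),
            class = "channel_mask")
}

relu <- function(x) { x[x < 0] <- 0; x }

# reusable conv workspace pair (one per branch)
fusion_workspaces <- function() {
  list(rgb = .branch_ws_new(), th = .branch_ws_new())
}

# global average pool over spatial axes, vectorized: returns N x C.
gap_pool <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(aperm(x, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4]))
  matrix(m, d[1], d[4])
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  D <- ncol(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. x_rgb: (N,S,S,3), x_th: (N,S,S,1), both in [0,1].
# Returns probabilities; with cache = TRUE also every intermediate needed
# by fusion_backward(). `ws` is a pair of reusable branch workspaces
# (created on the fly when NULL; a training loop passes persistent ones
# so conv buffers are allocated once).
fusion_forward <- function(model, x_rgb, x_th, cache = FALSE, ws = NULL,
                           want_a3 = FALSE) {
  p <- model$params
  cfg <- model$config
  if (is.null(ws)) ws <- fusion_workspaces()
  branch <- function(x, pre) {
    .branch_fwd(x,
                list(p[[paste0(pre, "_w1")]], p[[paste0(pre, "_w2")]],
                     p[[paste0(pre, "_w3")]]),
                list(p[[paste0(pre, "_b1")]], p[[paste0(pre, "_b2")]],
                     p[[paste0(pre, "_b3")]]),
                ws[[pre]], want_a3)
  }
  br <- branch(x_rgb, "rgb")
  bt <- branch(x_th, "th")
  th_out <- bt$out
  keep <- model$mask$keep %||% rep(TRUE, cfg$conv_filters[3])
  if (!all(keep)) {
    th_out <- sweep(th_out, 4, as.numeric(keep), "*")
  }
  g_rgb <- gap_pool(br$out)
  g_th <- gap_pool(th_out)
  fused <- cbind(g_rgb, g_th)                      # N x 2F
  N <- nrow(fused)
  Tn <- cfg$n_tokens; Td <- cfg$token_dim; D <- cfg$d_model
  # tokens: rows ordered (t fastest, then sample)
  tok <- matrix(t(fused), Td, Tn * N)              # cols (t, n)
  X0 <- t(tok) %*% p$embed_w +
    rep(p$embed_b, each = Tn * N)                  # (Tn*N) x D
  # multi-head self-attention per sample
  Q <- X0 %*% p$wq + rep(p$bq, each = Tn * N)
  K <- X0 %*% p$wk + rep(p$bk, each = Tn * N)
  V <- X0 %*% p$wv + rep(p$bv, each = Tn * N)
  hs <- D %/% cfg$n_heads
  att <- vector("list", N)
  AV <- matrix(0, Tn * N, D)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * Tn + seq_len(Tn)
    att[[n]] <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      cols <- (h - 1L) * hs + seq_len(hs)
      S <- Q[rows, cols, drop = FALSE] %*%
        t(K[rows, cols, drop = FALSE]) / sqrt(hs)
      A <- softmax_rows(S)
      att[[n]][[h]] <- A
      AV[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  O <- AV %*% p$wo + rep(p$bo, each = Tn * N)
  ln1 <- layernorm_fwd(X0 + O, p$ln1_g, p$ln1_b)
  H1 <- relu(ln1$y %*% p$ff_w1 + rep(p$ff_b1, each = Tn * N))
  F2 <- H1 %*% p$ff_w2 + rep(p$ff_b2, each = Tn * N)
  ln2 <- layernorm_fwd(ln1$y + F2, p$ln2_g, p$ln2_b)
  # flatten per sample: (Tn*N) x D -> N x (Tn*D), token-major
  flat <- matrix(aperm(array(ln2$y, c(Tn, N, D)), c(1, 3, 2)),
                 Tn * D, N)
  flat <- t(flat)
  Z1 <- relu(flat %*% p$dense_w + rep(p$dense_b, each = N))
  logits <- Z1 %*% p$head_w + rep(p$head_b, each = N)
  proba <- softmax_rows(logits)
  colnames(proba) <- model$classes
  if (!cache) return(list(proba = proba, logits = logits))
  list(proba = proba, logits = logits, ws = ws, br = br, bt = bt,
       keep = keep,
       g_rgb = g_rgb, g_th = g_th, fused = fused, X0 = X0, Q = Q, K = K,
       V = V, att = att, AV = AV, O = O, ln1 = ln1, H1 = H1, F2 = F2,
       ln2 = ln2, flat = flat, Z1 = Z1, N = N)
}

# Backward pass from d(loss)/d(logits). Returns gradients for every
# parameter plus d(loss)/d(a3) of each branch (the final conv
# activations, used by Grad-CAM).
fusion_backward <- function(model, cc, dlogits, want_da3 = FALSE) {
  p <- model$params
  cfg <- model$config
  N <- cc$N; Tn <- cfg$n_tokens; Td <- cfg$token_dim; D <- cfg$d_model
  g <- list()
  g$head_w <- t(cc$Z1) %*% dlogits
  g$head_b <- colSums(dlogits)
  dZ1 <- dlogits %*% t(p$head_w)
  dZ1[cc$Z1 <= 0] <- 0
  g$dense_w <- t(cc$flat) %*% dZ1
  g$dense_b <- colSums(dZ1)
  dflat <- dZ1 %*% t(p$dense_w)                    # N x (Tn*D)
  dy2 <- matrix(aperm(array(t(dflat), c(Tn, D, N)), c(1, 3, 2)), Tn * N, D)
  l2 <- layernorm_bwd(dy2, cc$ln2, p$ln2_g)
  g$ln2_g <- l2$dg; g$ln2_b <- l2$db
  dF2 <- l2$dx
  g$ff_w2 <- t(cc$H1) %*% dF2
  g$ff_b2 <- colSums(dF2)
  dH1 <- dF2 %*% t(p$ff_w2)
  dH1[cc$H1 <= 0] <- 0
  g$ff_w1 <- t(cc$ln1$y) %*% dH1
  g$ff_b1 <- colSums(dH1)
  dln1y <- l2$dx + dH1 %*% t(p$ff_w1)
  l1 <- layernorm_bwd(dln1y, cc$ln1, p$ln1_g)
  g$ln1_g <- l1$dg; g$ln1_b <- l1$db
  dO <- l1$dx
  g$wo <- t(cc$AV) %*% dO
  g$bo <- colSums(dO)
  dAV <- dO %*% t(p$wo)
  hs <- D %/% cfg$n_heads
  dQ <- matrix(0, Tn * N, D); dK <- dQ; dV <- dQ
  for (n in seq_len(N)) {
    rows <- (n - 1L) * Tn + seq_len(Tn)
    for (h in seq_len(cfg$n_heads)) {
      cols <- (h - 1L) * hs + seq_len(hs)
      A <- cc$att[[n]][[h]]
      dAVh <- dAV[rows, cols, drop = FALSE]
      Vh <- cc$V[rows, cols, drop = FALSE]
      dA <- dAVh %*% t(Vh)
      dV[rows, cols] <- t(A) %*% dAVh
      dS <- A * (dA - rowSums(dA * A))             # softmax jacobian
      dS <- dS / sqrt(hs)
      Qh <- cc$Q[rows, cols, drop = FALSE]
      Kh <- cc$K[rows, cols, drop = FALSE]
      dQ[rows, cols] <- dS %*% Kh
      dK[rows, cols] <- t(dS) %*% Qh
    }
  }
  g$wq <- t(cc$X0) %*% dQ; g$bq <- colSums(dQ)
  g$wk <- t(cc$X0) %*% dK; g$bk <- colSums(dK)
  g$wv <- t(cc$X0) %*% dV; g$bv <- colSums(dV)
  dX0 <- l1$dx + dQ %*% t(p$wq) + dK %*% t(p$wk) + dV %*% t(p$wv)
  tok <- matrix(t(cc$fused), Td, Tn * N)
  g$embed_w <- tok %*% dX0
  g$embed_b <- colSums(dX0)
  dtok <- dX0 %*% t(p$embed_w)                     # (Tn*N) x Td
  dfused <- t(matrix(t(dtok), Td * Tn, N))         # N x 2F
  Fc <- cfg$conv_filters[3]
  dg_rgb <- dfused[, seq_len(Fc), drop = FALSE]
  dg_th <- dfused[, Fc + seq_len(Fc), drop = FALSE]
  side3 <- cfg$input_side / 8L
  gap_bwd <- function(dgap) {
    # N x C -> (N, side3, side3, C), gradient spread uniformly
    arr <- array(0, c(N, side3, side3, Fc))
    sweep(arr, c(1, 4), dgap / (side3 * side3), "+")
  }
  dth_out <- gap_bwd(dg_th)
  if (!all(cc$keep)) dth_out <- sweep(dth_out, 4, as.numeric(cc$keep), "*")
  branch_bwd <- function(cc_b, dpool_out, pre) {
    bw <- .branch_bwd(cc$ws[[pre]],
                      list(p[[paste0(pre, "_w1")]], p[[paste0(pre, "_w2")]],
                           p[[paste0(pre, "_w3")]]),
                      dpool_out, want_da3)
    bg <- stats::setNames(
      list(bw$dw1, bw$db1, bw$dw2, bw$db2, bw$dw3, bw$db3),
      paste0(pre, c("_w1", "_b1", "_w2", "_b2", "_w3", "_b3")))
    list(grads = bg, da3 = bw$da3)
  }
  rb <- branch_bwd(cc$br, gap_bwd(dg_rgb), "rgb")
  tb <- branch_bwd(cc$bt, dth_out, "th")
  g <- c(g, rb$grads, tb$grads)
  list(grads = g, da3_rgb = rb$da3, da3_th = tb$da3)
}

#' Class probabilities from the fusion model
#'
#' @param model A trained [build_fusion_model()] object.
#' @param rgb Preprocessed RGB input (`side x side x 3` in `[0, 1]`, or a
#'   batch `N x side x side x 3`).
#' @param thermal Preprocessed thermal input (`side x side x 1`, or batch).
#' @return Probability matrix (rows sum to 1) with class column names.
#' @export
predict_proba <- function(model, rgb, thermal) {
  stopifnot(inherits(model, "fusion_model"))
  rgb <- as_batch(rgb, model$config$input_side, 3L)
  thermal <- as_batch(thermal, model$config$input_side, 1L)
  if (max(rgb) > 1 + 1e-9 || min(rgb) < -1e-9 ||
      max(thermal) > 1 + 1e-9 || min(thermal) < -1e-9) {
    stop_invalid("inputs look unpreprocessed (values outside [0, 1]); ",
                 "run preprocess_for_model() first")
  }
  n <- dim(rgb)[1]
  chunk <- model$config$batch_size
  if (n <= chunk) return(fusion_forward(model, rgb, thermal)$proba)
  ws <- fusion_workspaces()
  out <- matrix(0, n, model$config$n_classes,
                dimnames = list(NULL, model$classes))
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    out[b, ] <- fusion_forward(model, rgb[b, , , , drop = FALSE],
                               thermal[b, , , , drop = FALSE],
                               ws = ws)$proba
  }
  out
}

as_batch <- function(x, side, channels) {
  d <- dim(x)
  if (length(d) == 2L && channels == 1L) x <- array(x, c(d, 1L))
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(1L, d))
  d <- dim(x)
  if (length(d) != 4L || d[2] != side || d[3] != side || d[4] != channels) {
    stop_invalid("expected ", side, "x", side, "x", channels,
                 " input (or a batch of them); got dim ",
                 paste(dim(x), collapse = "x"))
  }
  x
}
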