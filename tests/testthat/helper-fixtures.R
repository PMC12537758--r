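# Shared fixtures, all generated in code.

# tiny fusion configuration for fast structural/gradient tests
tiny_fusion_config <- function(seed = 7L, n_classes = 3L) {
  fusion_config(input_side = 16L, conv_filters = c(2L, 3L, 4L),
                n_tokens = 2L, d_model = 8L, n_heads = 2L,
                ff_dim = 12L, dense_units = 10L, n_classes = n_classes,
                batch_size = 8L, seed = seed)
}

# small synthetic dataset shared across tests (cached per session)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_config(
        n_per_class = c(SD = 6, D = 6, O = 12, W = 6, SW = 6),
        stages = "early", seed = 123L))
    }
    cache
  }
})

# well-separated indicator table for classifier tests
make_indicator_table <- function(n_per_class = 20L, seed = 5L,
                                 stage = "early", separation = 1) {
  ds <- generate_dataset(generator_config(
    n_per_class = stats::setNames(rep(n_per_class, 5), stress_levels5()),
    stages = stage, separation = separation, seed = seed))
  do.call(rbind, lapply(ds$samples, function(s) s$indicators))
}

# flat RGB test card: constant color image
flat_rgb <- function(color, side = 32L) {
  px <- array(0, c(side, side, 3))
  for (ch in 1:3) px[, , ch] <- color[ch]
  rgb_image(px, range = "raw")
}

expect_validation_error <- function(expr) {
  expect_error(expr, class = "cwsifusion_validation_error")
}
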