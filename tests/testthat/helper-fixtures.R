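# Shared fixture builders; everything is generated in code at test time.

# A small pair with a rectangular lesion; deterministic.
toy_pair <- function(H = 16L, W = 16L, lesion = TRUE, id = "toy", seed = 1L) {
  img <- cytomtl:::with_seed(seed, array(stats::runif(H * W * 3), c(H, W, 3)))
  msk <- matrix(0L, H, W)
  if (lesion) msk[(H %/% 4):(H %/% 2), (W %/% 4):(W %/% 2)] <- 1L
  image_mask_pair(img, msk, id)
}

# Minimal transformer-free tiny config for fast forward/backward tests.
tt_config <- function(...) {
  model_config_tiny(input_size = c(16L, 16L, 3L), channels = c(4L, 8L),
                    embed_dim = 8L, depth = 1L, heads = 2L, patch_size = 2L,
                    mlp_hidden = 8L, ...)
}

expect_all_in <- function(x, lo, hi) {
  expect_true(min(x) >= lo && max(x) <= hi)
}
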