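# Architecture contracts: shapes, pooling-index bookkeeping, residual
# identity limit, head variants, determinism, checkpoints.

test_that("encoder halves resolution per block and returns all index sets", {
  m <- build_model(tt_config(seed = 1L))
  x <- cytomtl:::with_seed(2, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  st <- encoder_forward(m, x)
  expect_equal(dim(st$feature_map), c(4L, 4L, 8L, 2L))    # 16 / 2^2
  expect_length(st$pooling_indices, 2L)
  expect_length(st$skip_features, 2L)
  expect_equal(dim(st$skip_features[[1]])[1:2], c(16L, 16L))
  # three blocks give three index sets; 64 input with 3 pools ends at 8
  m3 <- build_model(model_config_tiny(seed = 1L))
  st3 <- encoder_forward(m3, array(0.5, c(64, 64, 3, 1)))
  expect_length(st3$pooling_indices, 3L)
  expect_equal(dim(st3$feature_map)[1:2], c(8L, 8L))
})

test_that("bridge preserves spatial dims and zeroed residuals act as identity", {
  m <- build_model(tt_config(seed = 3L))
  x <- cytomtl:::with_seed(4, array(runif(16 * 16 * 3 * 1), c(16, 16, 3, 1)))
  st <- encoder_forward(m, x)
  br <- bridge_forward(m, st$feature_map)
  expect_equal(dim(br), dim(st$feature_map))
  # zero the final conv of each bottleneck: with fresh running stats the
  # residual branch contributes exactly nothing, so stage output == input
  for (stg in m$bridge$stages) {
    stg$c3$params$W[] <- 0
    stg$c3$params$b[] <- 0
  }
  proj_only <- cytomtl:::run_seq(m$bridge$proj, cytomtl:::chw_in(st$feature_map), FALSE)
  br0 <- bridge_forward(m, st$feature_map)
  expect_equal(br0, cytomtl:::chw_out(proj_only), tolerance = 1e-12)
})

test_that("decoder restores input resolution with probabilities in (0,1)", {
  m <- build_model(tt_config(seed = 5L))
  x <- cytomtl:::with_seed(6, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  st <- encoder_forward(m, x)
  br <- bridge_forward(m, st$feature_map)
  mask <- decoder_forward(m, br)
  expect_equal(dim(mask), c(16L, 16L, 2L))
  expect_all_in(mask, 1e-12, 1 - 1e-12)
  # stage/index mismatch is rejected
  bad <- br[, 1:2, , , drop = FALSE]
  expect_error(decoder_forward(m, bad), "mismatch")
})

test_that("transformer head token count follows the patch arithmetic", {
  m <- build_model(tt_config(seed = 7L))             # grid 4x4, patch 2 -> 4+2 tokens
  expect_equal(m$cls_head$Tp, 4L)
  expect_equal(m$cls_head$nt, 2L)
  expect_equal(nrow(m$cls_head$tokens$params$pos), 6L)
  # the full-size configuration: 32x32 bridge map, patch 2 -> 258 tokens
  cfg <- model_config(seed = 1L)
  expect_equal((32L %/% cfg$patch_size)^2 + 2L, 258L)
  hd <- cytomtl:::with_seed(1, cytomtl:::vit_head_new(16L, c(32L, 32L), cfg, TRUE))
  expect_equal(hd$Tp + hd$nt, 258L)
  out <- deit_head_forward(m, bridge_forward(m, encoder_forward(
    m, array(0.5, c(16, 16, 3, 1)))$feature_map))
  expect_all_in(out$cls_prob, 1e-12, 1 - 1e-12)
  expect_all_in(out$dist_prob, 1e-12, 1 - 1e-12)
})

test_that("all four variants satisfy the dual-head output contract", {
  x <- cytomtl:::with_seed(8, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  params <- numeric(0)
  for (v in c("segnet_mlp", "segnet_resnet_mlp", "segnet_resnet_vit",
              "segnet_resnet_deit")) {
    m <- build_model(tt_config(variant = v, seed = 9L))
    out <- model_forward(m, x)
    expect_equal(dim(out$mask_prob), c(16L, 16L, 2L))
    expect_length(out$cls_prob, 2L)
    expect_all_in(out$mask_prob, 1e-12, 1 - 1e-12)
    expect_all_in(out$cls_prob, 1e-12, 1 - 1e-12)
    if (v == "segnet_resnet_deit") expect_length(out$dist_token_prob, 2L)
    else expect_null(out$dist_token_prob)
    params[v] <- count_parameters(m)
  }
  # each added component adds parameters; the encoder-only MLP is smallest
  expect_lt(params["segnet_mlp"], params["segnet_resnet_mlp"])
  expect_lt(params["segnet_resnet_mlp"], params["segnet_resnet_deit"])
  expect_lt(params["segnet_resnet_vit"], params["segnet_resnet_deit"])
  expect_error(tt_config(variant = "unknown"), "arg")
})

test_that("seeded builds and inference-mode forwards are deterministic", {
  c1 <- tt_config(seed = 11L)
  m1 <- build_model(c1); m2 <- build_model(c1)
  expect_identical(lapply(cytomtl:::collect_layers(m1), `[[`, "params"),
                   lapply(cytomtl:::collect_layers(m2), `[[`, "params"))
  x <- cytomtl:::with_seed(12, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  o1 <- model_forward(m1, x); o2 <- model_forward(m1, x)
  expect_identical(o1, o2)
  # batch independence in inference mode: sample 1 alone == sample 1 in batch
  single <- model_forward(m1, x[, , , 1, drop = FALSE])
  expect_equal(single$mask_prob[, , 1], o1$mask_prob[, , 1], tolerance = 1e-12)
  expect_equal(single$cls_prob, o1$cls_prob[1], tolerance = 1e-12)
})

test_that("gradients reach the encoder through bridge and both heads", {
  m <- build_model(tt_config(seed = 13L))
  x <- cytomtl:::with_seed(14, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  g <- array(0L, c(16, 16, 2)); g[4:8, 4:8, ] <- 1L
  out <- model_forward(m, x, training = TRUE)
  tl <- total_loss(out$mask_prob, g, out$cls_token_prob, c(1, 1),
                   loss_weights(), out$dist_token_prob, grad = TRUE)
  model_backward(m, tl$dmask, tl$dcls, tl$ddist)
  first_conv <- m$enc_blocks[[1]]$layers$conv
  expect_gt(sum(abs(first_conv$grads$W)), 0)
  tok <- m$cls_head$tokens
  expect_gt(sum(abs(tok$grads$cls)), 0)
  expect_gt(sum(abs(tok$grads$dist)), 0)
})

test_that("checkpoints round-trip weights, config and running stats", {
  m <- build_model(tt_config(seed = 15L))
  x <- cytomtl:::with_seed(16, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  # a training step so running stats differ from init
  out <- model_forward(m, x, training = TRUE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  o1 <- model_forward(m, x); o2 <- model_forward(m2, x)
  expect_equal(o1, o2, tolerance = 1e-15)
  # corrupt checkpoint is rejected
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(oops = 1), bad)
  expect_error(load_checkpoint(bad), "corrupt")
})
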