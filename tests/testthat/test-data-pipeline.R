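test_that("per-channel min-max normalization hits exact endpoints", {
  expect_equal(as.vector(normalize_image(array(c(0, 128, 255), c(3, 1, 1)))),
               c(0, 128 / 255, 1))
  # constant channel maps to zeros by convention
  expect_equal(as.vector(normalize_image(array(0, c(4, 4, 1)))), rep(0, 16))
  expect_equal(as.vector(normalize_image(array(7, c(2, 2, 1)))), rep(0, 4))
  # random uint8 image: every channel spans exactly [0, 1] afterwards
  img <- cytomtl:::with_seed(3, array(sample(0:255, 5 * 7 * 3, TRUE), c(5, 7, 3)))
  out <- normalize_image(img)
  for (c in 1:3) {
    expect_equal(min(out[, , c]), 0)
    expect_equal(max(out[, , c]), 1)
  }
  # idempotence up to floating tolerance
  expect_equal(normalize_image(out), out, tolerance = 1e-12)
})

test_that("image-level label derivation follows the any-foreground rule", {
  expect_identical(derive_label(matrix(0, 4, 4)), 0L)
  one <- matrix(0, 4, 4); one[2, 3] <- 1
  expect_identical(derive_label(one), 1L)
  expect_identical(derive_label(matrix(1, 4, 4)), 1L)
  expect_error(derive_label(matrix(0.5, 2, 2)), "binary")
})

test_that("paired resize keeps masks binary and re-derives the label", {
  p <- toy_pair(32L, 32L)
  same <- resize_pair(p, c(32L, 32L))
  expect_identical(same$image, p$image)
  expect_identical(same$mask, p$mask)
  down <- resize_pair(p, c(16L, 16L))
  expect_equal(dim(down$image), c(16L, 16L, 3L))
  expect_true(all(down$mask %in% c(0L, 1L)))
  expect_all_in(down$image, 0, 1)
  # checkerboard mask upscaled 2x stays binary
  cb <- image_mask_pair(array(0.5, c(8, 8, 3)),
                        (outer(1:8, 1:8, `+`) %% 2))
  up <- resize_pair(cb, c(16L, 16L))
  expect_setequal(unique(as.vector(up$mask)), c(0L, 1L))
  # a vanishing one-pixel lesion flips the label of the resized pair
  tiny <- matrix(0L, 64, 64); tiny[1, 64] <- 1L
  tp <- image_mask_pair(array(0.5, c(64, 64, 3)), tiny)
  expect_identical(tp$label, 1L)
  small <- resize_pair(tp, c(8L, 8L))
  expect_identical(small$label, derive_label(small$mask))
})

test_that("patch grids cover every pixel, clamped at the margins", {
  g1 <- build_patch_grid(c(256L, 256L), 256L, 256L)
  expect_equal(nrow(g1$origins), 1L)
  expect_equal(unname(g1$origins[1, ]), c(0L, 0L))

  g2 <- build_patch_grid(c(256L, 256L), 128L, 64L)
  expect_equal(nrow(g2$origins), 9L)          # 3 origins per axis
  expect_setequal(unique(g2$origins[, 1]), c(0L, 64L, 128L))

  g3 <- build_patch_grid(c(250L, 250L), 128L, 64L)
  expect_equal(max(g3$origins[, 1]), 122L)    # clamped to 250 - 128
  # brute-force coverage check over all pixels
  covered <- matrix(FALSE, 250, 250)
  for (i in seq_len(nrow(g3$origins))) {
    r <- g3$origins[i, 1]; cc <- g3$origins[i, 2]
    covered[(r + 1):(r + 128), (cc + 1):(cc + 128)] <- TRUE
  }
  expect_true(all(covered))
  expect_error(build_patch_grid(c(100L, 100L), 128L, 64L), "exceeds")
  expect_error(build_patch_grid(c(256L, 256L), 128L, 200L), "stride")
})

test_that("extracted patches match the grid windows", {
  p <- toy_pair(32L, 32L)
  g <- build_patch_grid(c(32L, 32L), 16L, 16L)
  patches <- extract_patches(p, g)
  expect_length(patches, 4L)
  expect_identical(patches[[1]]$image, p$image[1:16, 1:16, , drop = FALSE])
  expect_identical(patches[[4]]$mask, p$mask[17:32, 17:32])
})

test_that("augmentation applies one spatial transform to both image and mask", {
  H <- 16L; W <- 16L
  msk <- matrix(0L, H, W); msk[5, 3] <- 1L
  p <- image_mask_pair(array(0.5, c(H, W, 3)), msk)
  flipped <- augment_pair(p, params = list(hflip = TRUE))
  expect_equal(which(flipped$mask == 1, arr.ind = TRUE)[1, ],
               c(row = 5L, col = W - 3L + 1L))
  # neutral parameters give the identity
  id <- augment_pair(p, params = list())
  expect_identical(id$image, p$image)
  expect_identical(id$mask, p$mask)
  # same seed, same output; different seeds explore the parameter ranges
  a1 <- augment_pair(toy_pair(), seed = 7)
  a2 <- augment_pair(toy_pair(), seed = 7)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
})

test_that("random augmentations preserve value ranges and mask binarity", {
  p <- toy_pair(16L, 16L, seed = 9L)
  for (s in 1:50) {
    a <- augment_pair(p, seed = s)
    expect_all_in(a$image, 0, 1)
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_identical(a$label, derive_label(a$mask))
  }
})

test_that("stratified split reproduces the 80/20 arithmetic and conserves indices", {
  # 2227 items split 80/20 -> 1782 / 445, whatever the class composition
  for (npos in c(500L, 1113L, 1114L, 2000L)) {
    labs <- rep(c(1L, 0L), c(npos, 2227L - npos))
    sp <- stratified_split(labs, 0.8, seed = 4L)
    expect_length(sp$train, 1782L)
    expect_length(sp$validation, 445L)
    expect_setequal(c(sp$train, sp$validation), seq_len(2227L))
    expect_length(intersect(sp$train, sp$validation), 0L)
    # per-class proportions within one sample of the global fraction
    expect_lte(abs(sum(labs[sp$train] == 1) - 0.8 * npos), 1)
  }
  # all-same-class splits by count alone
  sp <- stratified_split(rep(1L, 10L), 0.8, seed = 1L)
  expect_length(sp$train, 8L)
  # 30 positives in 100 at 0.8 -> exactly 24 positives in train
  labs <- rep(c(1L, 0L), c(30L, 70L))
  sp <- stratified_split(labs, 0.8, seed = 2L)
  expect_equal(sum(labs[sp$train] == 1), 24L)
  expect_equal(sum(labs[sp$validation] == 1), 6L)
  # reproducibility and the under-2-members warning
  expect_identical(stratified_split(labs, 0.8, seed = 5L),
                   stratified_split(labs, 0.8, seed = 5L))
  expect_warning(stratified_split(c(1L, rep(0L, 9L)), 0.8, seed = 1L),
                 "fewer than 2")
})

test_that("fixture sets round-trip through PNG + manifest", {
  pairs <- generate_dataset(synth_config(n_images = 3, image_size = c(24, 24),
                                         seed = 5))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(pairs, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 6L)
  back <- read_dataset(manifest, normalize = FALSE)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, pairs[[i]]$mask)
    expect_identical(back[[i]]$label, pairs[[i]]$label)
    # images pass through 8-bit PNG quantization
    expect_lt(max(abs(back[[i]]$image - pairs[[i]]$image)), 1 / 254)
  }
  expect_error(write_fixture_set(list(), dir), "empty")
})
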