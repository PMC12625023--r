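# Pooling/unpooling contracts and hand-written backward passes checked
# against central finite differences.

test_that("max pooling records argmax positions with row-major tie-breaks", {
  r <- max_pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE))
  expect_equal(as.vector(r$out), 4)
  expect_equal(as.vector(r$k), 4L)            # (1,1) offset in row-major order
  # constant input: first occurrence wins
  rc <- max_pool_with_indices(matrix(5, 4, 4))
  expect_true(all(rc$k == 1L))
  expect_true(all(rc$out == 5))
})

test_that("unpooling restores pooled values to their recorded positions", {
  k <- array(4L, c(1, 1, 1, 1))
  z <- max_unpool(array(4, c(1, 1, 1, 1)), k, c(2L, 2L))
  expect_equal(z[, , 1, 1], matrix(c(0, 0, 0, 4), 2, 2))
  expect_equal(max_unpool(array(0, c(2, 2, 1, 1)), array(1L, c(2, 2, 1, 1)),
                          c(4L, 4L)),
               array(0, c(4, 4, 1, 1)))
  expect_error(max_unpool(array(1, c(1, 1, 1, 1)), array(5L, c(1, 1, 1, 1)),
                          c(2L, 2L)), "range")
})

test_that("pool/unpool duality holds on random maps (brute-force oracle)", {
  for (s in 1:5) {
    # non-negative maps (the post-ReLU regime where the re-pool identity holds)
    x <- cytomtl:::with_seed(s, array(runif(8 * 8 * 2 * 2, 0.01, 1), c(8, 8, 2, 2)))
    r <- max_pool_with_indices(x)
    u <- max_unpool(r$out, r$k, dim(x))
    # per-window brute force: pooled value sits at its argmax, zeros elsewhere
    for (ch in 1:2) for (n in 1:2) for (i in 1:4) for (j in 1:4) {
      win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch, n]
      uwin <- u[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch, n]
      expect_equal(max(win), r$out[i, j, ch, n])
      expect_equal(sum(uwin != 0), 1L)
      expect_equal(max(uwin), max(win))
    }
    # unpooled mass equals pooled mass; pool(unpool(pool)) == pool
    expect_equal(sum(u), sum(r$out))
    expect_equal(max_pool_with_indices(u)$out, r$out)
  }
})

numgrad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

test_that("convolution backward matches finite differences", {
  l <- cytomtl:::with_seed(1, cytomtl:::conv2d_new(2, 3, 3))
  x <- cytomtl:::with_seed(2, array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2)))
  dy <- cytomtl:::with_seed(3, array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2)))
  invisible(cytomtl:::conv2d_forward(l, x, training = TRUE))
  dx <- cytomtl:::conv2d_backward(l, dy)
  f <- function(xv) sum(cytomtl:::conv2d_forward(l, array(xv, dim(x))) * dy)
  idx <- c(1, 17, 50, 100, 144)
  expect_equal(dx[idx], numgrad(f, x, idx), tolerance = 1e-6)
  # weight gradient
  invisible(cytomtl:::conv2d_forward(l, x, training = TRUE))
  invisible(cytomtl:::conv2d_backward(l, dy))
  W0 <- l$params$W
  fw <- function(wv) {
    l$params$W <- matrix(wv, nrow = 3)
    on.exit(l$params$W <- W0)
    sum(cytomtl:::conv2d_forward(l, x) * dy)
  }
  idx <- c(1, 10, 25, 54)
  expect_equal(l$grads$W[idx], numgrad(fw, W0, idx), tolerance = 1e-6)
})

test_that("batch-norm and layer-norm backward match finite differences", {
  b <- cytomtl:::bn_new(3)
  x <- cytomtl:::with_seed(4, array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2)))
  dy <- cytomtl:::with_seed(5, array(rnorm(length(x)), dim(x)))
  invisible(cytomtl:::bn_forward(b, x, training = TRUE))
  dx <- cytomtl:::bn_backward(b, dy)
  f <- function(xv) sum(cytomtl:::bn_forward(b, array(xv, dim(x)), training = TRUE) * dy)
  idx <- c(2, 30, 60, 96)
  expect_equal(dx[idx], numgrad(f, x, idx, eps = 1e-5), tolerance = 1e-4)

  ln <- cytomtl:::layernorm_new(6)
  xt <- cytomtl:::with_seed(6, array(rnorm(5 * 6 * 2), c(5, 6, 2)))
  dyt <- cytomtl:::with_seed(7, array(rnorm(length(xt)), dim(xt)))
  invisible(cytomtl:::layernorm_forward(ln, xt, TRUE))
  dxt <- cytomtl:::layernorm_backward(ln, dyt)
  fl <- function(xv) sum(cytomtl:::layernorm_forward(ln, array(xv, dim(xt))) * dyt)
  idx <- c(1, 20, 45, 60)
  expect_equal(dxt[idx], numgrad(fl, xt, idx, eps = 1e-5), tolerance = 1e-4)
})

test_that("self-attention is permutation-equivariant and differentiable", {
  a <- cytomtl:::with_seed(8, cytomtl:::mhsa_new(8, 2))
  x <- cytomtl:::with_seed(9, array(rnorm(6 * 8 * 1), c(6, 8, 1)))
  y <- cytomtl:::mhsa_forward(a, x)
  # permute token order: output permutes identically (no positional bias)
  perm <- c(3, 1, 6, 2, 5, 4)
  yp <- cytomtl:::mhsa_forward(a, x[perm, , , drop = FALSE])
  expect_equal(yp[, , 1], y[perm, , 1], tolerance = 1e-12)
  # finite-difference gradient
  dy <- cytomtl:::with_seed(10, array(rnorm(length(y)), dim(y)))
  invisible(cytomtl:::mhsa_forward(a, x, TRUE))
  dx <- cytomtl:::mhsa_backward(a, dy)
  f <- function(xv) sum(cytomtl:::mhsa_forward(a, array(xv, dim(x))) * dy)
  idx <- c(1, 13, 29, 48)
  expect_equal(dx[idx], numgrad(f, x, idx), tolerance = 1e-5)
})
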