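# Convolutional building blocks with hand-written backward passes.
#
# Internal feature maps are dense arrays of dim c(C, H, W, N) (channels
# first): with channels as the fastest-varying dimension, the im2col
# matrix for a convolution is a plain reshape of each shifted slice — no
# transposes — and one BLAS matrix product does the work. Each layer is an
# environment holding $params (named list of numeric arrays), $grads
# (same shapes, filled by the backward pass) and a forward cache.
#
# The exported pooling/unpooling operations use the user-facing
# (H, W, C, N) orientation; the internal layers use channel-first twins.

new_layer <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$params <- list()
  self$grads <- list()
  class(self) <- c(type, "nn_layer")
  self
}

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

# -- 2D convolution (square kernel, stride 1, zero padding keeps dims) -------

conv2d_new <- function(in_ch, out_ch, k = 3L, pad = (k - 1L) %/% 2L) {
  self <- new_layer("conv2d")
  self$k <- as.integer(k); self$pad <- as.integer(pad)
  self$in_ch <- in_ch; self$out_ch <- out_ch
  fan_in <- k * k * in_ch
  # W rows = output channels; columns ordered kernel-offset-major, input
  # channel fastest, matching the im2col row layout below.
  self$params <- list(
    W = matrix(he_init(out_ch * fan_in, fan_in), nrow = out_ch),
    b = numeric(out_ch))
  self
}

conv2d_forward <- function(self, x, training = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  if (C != self$in_ch) stop("conv2d: expected ", self$in_ch, " channels, got ", C)
  k <- self$k; p <- self$pad
  if (p > 0) {
    xp <- array(0, c(C, H + 2 * p, W + 2 * p, N))
    xp[, (p + 1):(p + H), (p + 1):(p + W), ] <- x
  } else xp <- x
  Ho <- H + 2 * p - k + 1L; Wo <- W + 2 * p - k + 1L
  M <- Ho * Wo * N
  if (k == 1L) {
    Xcol <- matrix(xp, nrow = C)
  } else {
    Xcol <- matrix(0, k * k * C, M)
    o <- 0L
    for (kj in 1:k) for (ki in 1:k) {
      Xcol[(o * C + 1):(o * C + C), ] <-
        xp[, ki:(ki + Ho - 1), kj:(kj + Wo - 1), , drop = FALSE]
      o <- o + 1L
    }
  }
  y <- self$params$W %*% Xcol + self$params$b
  if (training) self$cache <- list(Xcol = Xcol, H = H, W = W, C = C, N = N,
                                   Ho = Ho, Wo = Wo)
  array(y, c(self$out_ch, Ho, Wo, N))
}

conv2d_backward <- function(self, dy) {
  ca <- self$cache
  k <- self$k; p <- self$pad; C <- ca$C; N <- ca$N
  dY <- matrix(dy, nrow = self$out_ch)
  self$grads$b <- rowSums(dY)
  self$grads$W <- tcrossprod(dY, ca$Xcol)
  dXcol <- crossprod(self$params$W, dY)
  if (k == 1L) {
    dxp <- array(dXcol, c(C, ca$Ho, ca$Wo, N))
    self$cache <- NULL
    return(dxp)
  }
  Hp <- ca$H + 2 * p; Wp <- ca$W + 2 * p
  dxp <- array(0, c(C, Hp, Wp, N))
  o <- 0L
  for (kj in 1:k) for (ki in 1:k) {
    hr <- ki:(ki + ca$Ho - 1); wr <- kj:(kj + ca$Wo - 1)
    dxp[, hr, wr, ] <- dxp[, hr, wr, , drop = FALSE] +
      array(dXcol[(o * C + 1):(o * C + C), ], c(C, ca$Ho, ca$Wo, N))
    o <- o + 1L
  }
  self$cache <- NULL
  if (p > 0) dxp[, (p + 1):(p + ca$H), (p + 1):(p + ca$W), , drop = FALSE] else dxp
}

# -- Batch normalization (per channel over H, W, N) ---------------------------

bn_new <- function(ch, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("bn")
  self$ch <- ch; self$momentum <- momentum; self$eps <- eps
  self$params <- list(gamma = rep(1, ch), beta = rep(0, ch))
  self$running_mean <- rep(0, ch)
  self$running_var <- rep(1, ch)
  self
}

# With channels first, per-channel vectors recycle along the first
# dimension of the (C, H*W*N) matrix view, so no sweeps are needed.
bn_forward <- function(self, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, nrow = self$ch)
  training <- training && !isTRUE(self$frozen)   # frozen: running stats as constants
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc^2)
    mom <- self$momentum
    self$running_mean <- (1 - mom) * self$running_mean + mom * mu
    self$running_var <- (1 - mom) * self$running_var + mom * v
  } else {
    mu <- self$running_mean
    v <- self$running_var
    xc <- xm - mu
  }
  invstd <- 1 / sqrt(v + self$eps)
  xhat <- xc * invstd
  ym <- xhat * self$params$gamma + self$params$beta
  self$cache <- list(xhat = xhat, invstd = invstd, d = d, training = training)
  array(ym, d)
}

bn_backward <- function(self, dy) {
  ca <- self$cache; d <- ca$d
  dym <- matrix(dy, nrow = self$ch)
  self$grads$gamma <- rowSums(dym * ca$xhat)
  self$grads$beta <- rowSums(dym)
  dxhat <- dym * self$params$gamma
  if (ca$training) {
    dxm <- (dxhat - rowMeans(dxhat) - ca$xhat * rowMeans(dxhat * ca$xhat)) * ca$invstd
  } else {
    dxm <- dxhat * ca$invstd
  }
  self$cache <- NULL
  array(dxm, d)
}

# -- Elementwise activations --------------------------------------------------

relu_new <- function() new_layer("relu")

relu_forward <- function(self, x, training = FALSE) {
  y <- x * (x > 0)
  self$cache <- (x > 0)
  y
}

relu_backward <- function(self, dy) {
  dx <- dy * self$cache
  self$cache <- NULL
  dx
}

sigmoid_new <- function() new_layer("sigmoid")

sigmoid_forward <- function(self, x, training = FALSE) {
  y <- 1 / (1 + exp(-x))
  self$cache <- y
  y
}

sigmoid_backward <- function(self, dy) {
  y <- self$cache
  self$cache <- NULL
  dy * y * (1 - y)
}

# -- Dropout (inverted scaling; identity at inference) ------------------------

dropout_new <- function(rate) {
  self <- new_layer("dropout")
  self$rate <- rate
  self
}

dropout_forward <- function(self, x, training = FALSE) {
  if (!training || self$rate <= 0) { self$cache <- NULL; return(x) }
  keep <- 1 - self$rate
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim(x) %||% length(x))
  self$cache <- mask
  x * mask
}

dropout_backward <- function(self, dy) {
  if (is.null(self$cache)) return(dy)
  dx <- dy * self$cache
  self$cache <- NULL
  dx
}

# -- 2x2 max pooling with argmax indices, and index-guided unpooling ----------

# Generic worker: `sd` names the two spatial dims of `x` (c(1,2) for the
# exported HWCN orientation, c(2,3) for the internal CHWN layout).
pool22 <- function(x, sd) {
  d <- dim(x)
  H <- d[sd[1]]; W <- d[sd[2]]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("max pooling requires even spatial dims")
  ix <- function(r, cc) {
    idx <- rep(list(quote(expr = )), length(d))
    idx[[sd[1]]] <- r; idx[[sd[2]]] <- cc
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  a <- ix(ro, co)    # window offset (0,0); candidates in row-major order
  b <- ix(ro, ce)    # (0,1)
  cc <- ix(re, co)   # (1,0)
  dd <- ix(re, ce)   # (1,1)
  m <- a; k <- array(1L, dim(a))
  u <- b > m;  m[u] <- b[u];  k[u] <- 2L
  u <- cc > m; m[u] <- cc[u]; k[u] <- 3L
  u <- dd > m; m[u] <- dd[u]; k[u] <- 4L
  list(out = m, k = k, dims = d)
}

# Flat positions (into an array of dim `dims`) encoded by pooling indices,
# for spatial dims `sd` of a 4D array.
unpool_flat_index <- function(k, dims, sd) {
  H <- dims[sd[1]]; W <- dims[sd[2]]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  kv <- as.vector(k)
  dr <- (kv - 1L) %/% 2L
  dc <- (kv - 1L) %% 2L
  # strides of the full-size array
  str <- cumprod(c(1, dims[-length(dims)]))
  pd <- dims; pd[sd] <- c(H2, W2)              # pooled dims
  pstr <- cumprod(c(1, pd[-length(pd)]))
  n <- prod(pd)
  coord <- function(axis) (seq_len(n) - 1L) %/% pstr[axis] %% pd[axis]
  idx <- numeric(n)
  for (axis in seq_along(dims)) {
    co <- coord(axis)
    if (axis == sd[1]) co <- co * 2L + dr
    else if (axis == sd[2]) co <- co * 2L + dc
    idx <- idx + co * str[axis]
  }
  idx + 1
}

#' Max pooling with preserved argmax indices
#'
#' Non-overlapping 2x2 max pooling over a `H x W x C x N` array (2D and 3D
#' inputs are treated as single-channel/single-sample). The argmax
#' position of every pooled window is recorded (ties broken by the first
#' occurrence in row-major window order), so the decoder can later restore
#' each value to exactly the location it came from.
#'
#' @param x numeric array with even spatial dims.
#' @return list with `out` (halved spatial dims), `k` (integer array of
#'   the same shape: window-internal argmax in 1..4, row-major) and `dims`
#'   (the input dimensions).
#' @export
max_pool_with_indices <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("x must be a matrix or array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3) dim(x) <- c(dim(x), 1L)
  pool22(x, c(1L, 2L))
}

#' Index-guided unpooling
#'
#' Sparse 2x upsampling: each pooled value is written back to the argmax
#' position recorded by [max_pool_with_indices()]; all other positions are
#' zero.
#'
#' @param x pooled array `H/2 x W/2 x C x N`.
#' @param indices integer array `k` returned by [max_pool_with_indices()].
#' @param output_dims integer vector, the pre-pool dimensions.
#' @return numeric array of dim `output_dims`.
#' @export
max_unpool <- function(x, indices, output_dims) {
  if (length(output_dims) == 2) output_dims <- c(output_dims, 1L, 1L)
  if (length(output_dims) == 3) output_dims <- c(output_dims, 1L)
  if (is.null(dim(x))) stop("x must be an array")
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (!all(dim(indices) == dim(x)))
    stop("indices and input shapes differ")
  if (any(indices < 1L | indices > 4L)) stop("index out of range")
  if (length(x) * 4L != prod(output_dims))
    stop("output_dims incompatible with input size")
  z <- array(0, output_dims)
  z[unpool_flat_index(indices, output_dims, c(1L, 2L))] <- as.vector(x)
  z
}

# Channel-first twins used inside the network.
pool_layer_new <- function() new_layer("maxpool")

pool_layer_forward <- function(self, x, training = FALSE) {
  r <- pool22(x, c(2L, 3L))
  self$k <- r$k
  self$dims <- r$dims
  r$out
}

pool_layer_backward <- function(self, dy) {
  z <- array(0, self$dims)
  z[unpool_flat_index(self$k, self$dims, c(2L, 3L))] <- as.vector(dy)
  z
}

unpool_layer_new <- function() new_layer("unpool")

# `k`/`dims` are wired in from the matching encoder pool at forward time.
unpool_layer_forward <- function(self, x, training = FALSE) {
  if (is.null(self$k)) stop("unpool: no pooling indices attached")
  if (!all(dim(x) == dim(self$k)))
    stop("unpool: stage/index shape mismatch")
  z <- array(0, self$dims)
  z[unpool_flat_index(self$k, self$dims, c(2L, 3L))] <- as.vector(x)
  z
}

unpool_layer_backward <- function(self, dy) {
  array(dy[unpool_flat_index(self$k, self$dims, c(2L, 3L))], dim(self$k))
}

# Single dispatch table keeps train loops free of method lookup noise.
layer_forward <- function(self, x, training = FALSE) {
  switch(self$type,
    conv2d = conv2d_forward(self, x, training),
    bn = bn_forward(self, x, training),
    relu = relu_forward(self, x, training),
    sigmoid = sigmoid_forward(self, x, training),
    dropout = dropout_forward(self, x, training),
    maxpool = pool_layer_forward(self, x, training),
    unpool = unpool_layer_forward(self, x, training),
    dense = dense_forward(self, x, training),
    layernorm = layernorm_forward(self, x, training),
    gelu = gelu_forward(self, x, training),
    mhsa = mhsa_forward(self, x, training),
    stop("unknown layer type: ", self$type))
}

layer_backward <- function(self, dy) {
  switch(self$type,
    conv2d = conv2d_backward(self, dy),
    bn = bn_backward(self, dy),
    relu = relu_backward(self, dy),
    sigmoid = sigmoid_backward(self, dy),
    dropout = dropout_backward(self, dy),
    maxpool = pool_layer_backward(self, dy),
    unpool = unpool_layer_backward(self, dy),
    dense = dense_backward(self, dy),
    layernorm = layernorm_backward(self, dy),
    gelu = gelu_backward(self, dy),
    mhsa = mhsa_backward(self, dy),
    stop("unknown layer type: ", self$type))
}
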