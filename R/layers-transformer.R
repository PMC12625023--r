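# Transformer building blocks. Token batches are arrays of dim c(T, D, N)
# (tokens, embedding, batch); dense/layernorm/gelu also accept plain (N, D)
# matrices so the same layers serve the MLP classification heads.

tok2mat <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
}

mat2tok <- function(m, d) {
  if (length(d) == 2) return(m)
  aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
}

# -- Dense (affine) -----------------------------------------------------------

dense_new <- function(in_dim, out_dim) {
  self <- new_layer("dense")
  self$in_dim <- in_dim; self$out_dim <- out_dim
  self$params <- list(
    W = matrix(he_init(in_dim * out_dim, in_dim), nrow = in_dim),
    b = numeric(out_dim))
  self
}

dense_forward <- function(self, x, training = FALSE) {
  d <- if (is.matrix(x)) dim(x) else dim(x)
  xm <- tok2mat(x)
  y <- sweep(xm %*% self$params$W, 2, self$params$b, `+`)
  self$cache <- list(xm = xm, d = d)
  mat2tok(y, c(d[1], self$out_dim, d[3])[seq_along(d)])
}

dense_backward <- function(self, dy) {
  ca <- self$cache
  dym <- tok2mat(dy)
  self$grads$W <- crossprod(ca$xm, dym)
  self$grads$b <- colSums(dym)
  dx <- tcrossprod(dym, self$params$W)
  self$cache <- NULL
  mat2tok(dx, ca$d)
}

# -- Layer normalization over the embedding dimension -------------------------

layernorm_new <- function(dim, eps = 1e-5) {
  self <- new_layer("layernorm")
  self$dim <- dim; self$eps <- eps
  self$params <- list(gamma = rep(1, dim), beta = rep(0, dim))
  self
}

layernorm_forward <- function(self, x, training = FALSE) {
  d <- dim(x)
  xm <- tok2mat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + self$eps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2, self$params$gamma, `*`), 2, self$params$beta, `+`)
  self$cache <- list(xhat = xhat, invstd = invstd, d = d)
  mat2tok(y, d)
}

layernorm_backward <- function(self, dy) {
  ca <- self$cache
  dym <- tok2mat(dy)
  self$grads$gamma <- colSums(dym * ca$xhat)
  self$grads$beta <- colSums(dym)
  dxhat <- sweep(dym, 2, self$params$gamma, `*`)
  dxm <- (dxhat - rowMeans(dxhat) - ca$xhat * rowMeans(dxhat * ca$xhat)) * ca$invstd
  self$cache <- NULL
  mat2tok(dxm, ca$d)
}

# -- GELU (exact, via the normal CDF) -----------------------------------------

gelu_new <- function() new_layer("gelu")

gelu_forward <- function(self, x, training = FALSE) {
  self$cache <- x
  x * stats::pnorm(x)
}

gelu_backward <- function(self, dy) {
  x <- self$cache
  self$cache <- NULL
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# -- Multi-head self-attention ------------------------------------------------

mhsa_new <- function(embed_dim, heads) {
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  self <- new_layer("mhsa")
  self$D <- embed_dim; self$h <- heads; self$dh <- embed_dim %/% heads
  mk <- function() matrix(he_init(embed_dim^2, embed_dim), nrow = embed_dim)
  self$params <- list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
                      bq = numeric(embed_dim), bk = numeric(embed_dim),
                      bv = numeric(embed_dim), bo = numeric(embed_dim))
  self
}

mhsa_forward <- function(self, x, training = FALSE) {
  d <- dim(x); Tn <- d[1]; D <- d[2]; N <- d[3]
  P <- self$params; h <- self$h; dh <- self$dh
  y <- array(0, d)
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    X <- x[, , n]
    Q <- sweep(X %*% P$Wq, 2, P$bq, `+`)
    K <- sweep(X %*% P$Wk, 2, P$bk, `+`)
    V <- sweep(X %*% P$Wv, 2, P$bv, `+`)
    O <- matrix(0, Tn, D)
    Ah <- vector("list", h)
    for (i in seq_len(h)) {
      ci <- ((i - 1) * dh + 1):(i * dh)
      A <- softmax_rows(tcrossprod(Q[, ci, drop = FALSE], K[, ci, drop = FALSE]) / sqrt(dh))
      O[, ci] <- A %*% V[, ci, drop = FALSE]
      Ah[[i]] <- A
    }
    y[, , n] <- sweep(O %*% P$Wo, 2, P$bo, `+`)
    cache[[n]] <- list(X = X, Q = Q, K = K, V = V, A = Ah, O = O)
  }
  self$cache <- cache
  y
}

mhsa_backward <- function(self, dy) {
  P <- self$params; h <- self$h; dh <- self$dh
  d <- dim(dy); N <- d[3]
  g <- lapply(P, function(p) p * 0)
  dx <- array(0, c(d[1], self$D, N))
  for (n in seq_len(N)) {
    ca <- self$cache[[n]]
    dY <- dy[, , n]
    g$Wo <- g$Wo + crossprod(ca$O, dY)
    g$bo <- g$bo + colSums(dY)
    dO <- tcrossprod(dY, P$Wo)
    dQ <- matrix(0, d[1], self$D); dK <- dQ; dV <- dQ
    for (i in seq_len(h)) {
      ci <- ((i - 1) * dh + 1):(i * dh)
      A <- ca$A[[i]]
      dOh <- dO[, ci, drop = FALSE]
      dA <- tcrossprod(dOh, ca$V[, ci, drop = FALSE])
      dV[, ci] <- crossprod(A, dOh)
      dS <- (dA - rowSums(dA * A)) * A / sqrt(dh)
      dQ[, ci] <- dS %*% ca$K[, ci, drop = FALSE]
      dK[, ci] <- crossprod(dS, ca$Q[, ci, drop = FALSE])
    }
    g$Wq <- g$Wq + crossprod(ca$X, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(ca$X, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(ca$X, dV); g$bv <- g$bv + colSums(dV)
    dx[, , n] <- tcrossprod(dQ, P$Wq) + tcrossprod(dK, P$Wk) + tcrossprod(dV, P$Wv)
  }
  self$grads <- g
  self$cache <- NULL
  dx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
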