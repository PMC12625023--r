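# The hybrid multi-task network: a convolutional encoder that preserves
# max-pooling indices, a bottleneck residual feature bridge, an
# index-guided unpooling decoder ending in a 1x1 convolution + sigmoid
# (pixel-wise lesion probability), and a classification head — either a
# global-average-pool MLP or a patch-token transformer with class token
# and, in the full variant, a DeiT-style distillation token.

MODEL_VARIANTS <- c("segnet_mlp", "segnet_resnet_mlp", "segnet_resnet_vit",
                    "segnet_resnet_deit")

#' Model configuration
#'
#' @param input_size integer vector `(H, W, C)`. `H` and `W` must be
#'   divisible by `2^length(channels)` (one 2x pooling per encoder block).
#' @param channels output channels of each encoder block (doubling by
#'   default, mirrored by the decoder).
#' @param convs_per_block 3x3 conv/BN/ReLU repetitions per encoder block.
#' @param bridge_stages number of bottleneck residual stages (1x1 reduce,
#'   3x3, 1x1 expand, shortcut add) in the feature bridge.
#' @param patch_size transformer patch size on the bridge feature map; the
#'   bridge map dims must be divisible by it.
#' @param embed_dim,depth,heads transformer width, number of pre-norm
#'   blocks, and attention heads.
#' @param mlp_hidden hidden width of the MLP classification head variants.
#' @param dropout dropout rate, applied in the decoder and classifier head.
#' @param variant one of `"segnet_mlp"` (no bridge, GAP+MLP head),
#'   `"segnet_resnet_mlp"` (bridge + MLP head), `"segnet_resnet_vit"`
#'   (bridge + transformer head, class token only) or
#'   `"segnet_resnet_deit"` (full model, class + distillation tokens).
#' @param skip_add additionally add encoder pre-pool feature maps into the
#'   decoder after each unpooling (pooling indices always flow regardless).
#' @param seed optional integer; makes weight initialization reproducible.
#' @return a validated `model_config` list.
#' @export
model_config <- function(input_size = c(256L, 256L, 3L),
                         channels = c(64L, 128L, 256L),
                         convs_per_block = 2L,
                         bridge_stages = 2L,
                         patch_size = 2L,
                         embed_dim = 192L,
                         depth = 4L,
                         heads = 3L,
                         mlp_hidden = 128L,
                         dropout = 0.3,
                         variant = "segnet_resnet_deit",
                         skip_add = FALSE,
                         seed = NULL) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  nb <- length(channels)
  H <- input_size[1]; W <- input_size[2]
  if (H %% 2^nb != 0 || W %% 2^nb != 0)
    stop("input H and W must be divisible by 2^", nb)
  if (variant %in% c("segnet_resnet_vit", "segnet_resnet_deit")) {
    if ((H %/% 2^nb) %% patch_size != 0 || (W %/% 2^nb) %% patch_size != 0)
      stop("bridge feature map dims must be divisible by patch_size")
    if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  }
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 convs_per_block = as.integer(convs_per_block),
                 bridge_stages = as.integer(bridge_stages),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout = dropout, variant = variant,
                 skip_add = isTRUE(skip_add), seed = seed),
            class = "model_config")
}

#' Small configuration for CPU-scale experiments
#'
#' 64x64 RGB input, channels 8/16/32, a 2-block 32-dim transformer. Used
#' throughout the test-suite and the scaled-down capability runs.
#' @param ... overrides passed on to [model_config()].
#' @export
model_config_tiny <- function(...) {
  args <- list(input_size = c(64L, 64L, 3L), channels = c(8L, 16L, 32L),
               bridge_stages = 2L, patch_size = 2L, embed_dim = 32L,
               depth = 2L, heads = 2L, mlp_hidden = 32L, dropout = 0)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

conv_bn_relu <- function(in_ch, out_ch, k = 3L) {
  list(conv = conv2d_new(in_ch, out_ch, k), bn = bn_new(out_ch), relu = relu_new())
}

bottleneck_new <- function(ch, mid = max(1L, ch %/% 4L)) {
  list(c1 = conv2d_new(ch, mid, 1L), b1 = bn_new(mid), r1 = relu_new(),
       c2 = conv2d_new(mid, mid, 3L), b2 = bn_new(mid), r2 = relu_new(),
       c3 = conv2d_new(mid, ch, 1L), b3 = bn_new(ch), r_out = relu_new())
}

vit_head_new <- function(in_ch, grid_hw, cfg, use_dist) {
  p <- cfg$patch_size; D <- cfg$embed_dim
  Tp <- (grid_hw[1] %/% p) * (grid_hw[2] %/% p)
  nt <- if (use_dist) 2L else 1L
  tok <- new_layer("ptokens")
  tok$params <- list(cls = stats::rnorm(D, sd = 0.02),
                     pos = matrix(stats::rnorm((Tp + nt) * D, sd = 0.02), Tp + nt, D))
  if (use_dist) tok$params$dist <- stats::rnorm(D, sd = 0.02)
  blocks <- lapply(seq_len(cfg$depth), function(i) {
    list(ln1 = layernorm_new(D), attn = mhsa_new(D, cfg$heads),
         ln2 = layernorm_new(D), fc1 = dense_new(D, 4L * D), act = gelu_new(),
         fc2 = dense_new(4L * D, D))
  })
  list(type = "vit", p = p, D = D, Tp = Tp, nt = nt, use_dist = use_dist,
       grid = grid_hw, in_ch = in_ch,
       embed = dense_new(p * p * in_ch, D), tokens = tok, blocks = blocks,
       ln_f = layernorm_new(D),
       drop_cls = dropout_new(cfg$dropout),
       head_cls = dense_new(D, 1L),
       drop_dist = if (use_dist) dropout_new(cfg$dropout),
       head_dist = if (use_dist) dense_new(D, 1L))
}

mlp_head_new <- function(in_ch, cfg) {
  list(type = "mlp", in_ch = in_ch,
       fc1 = dense_new(in_ch, cfg$mlp_hidden), act = relu_new(),
       drop = dropout_new(cfg$dropout), fc2 = dense_new(cfg$mlp_hidden, 1L))
}

#' Build a network from a configuration
#'
#' Constructs the requested ablation variant with He-initialized weights.
#' With `config$seed` set, two builds produce identical initial weights.
#'
#' @param config a [model_config()].
#' @return a model environment; see [model_forward()].
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  builder <- function() build_model_impl(config)
  if (!is.null(config$seed)) with_seed(config$seed, builder()) else builder()
}

build_model_impl <- function(cfg) {
  m <- new.env(parent = emptyenv())
  m$config <- cfg
  ch <- cfg$channels; nb <- length(ch)
  in_ch <- cfg$input_size[3]
  # encoder
  m$enc_blocks <- vector("list", nb)
  prev <- in_ch
  for (i in seq_len(nb)) {
    layers <- list()
    cin <- prev
    for (j in seq_len(cfg$convs_per_block)) {
      layers <- c(layers, conv_bn_relu(cin, ch[i]))
      cin <- ch[i]
    }
    m$enc_blocks[[i]] <- list(layers = layers, pool = pool_layer_new())
    prev <- ch[i]
  }
  cN <- ch[nb]
  # bridge (absent in the encoder-only ablation)
  if (cfg$variant != "segnet_mlp") {
    m$bridge <- list(proj = conv_bn_relu(cN, cN, 1L),
                     stages = lapply(seq_len(cfg$bridge_stages),
                                     function(i) bottleneck_new(cN)))
  } else m$bridge <- NULL
  # decoder: unpool (deepest indices first) then conv refinement
  m$dec_stages <- vector("list", nb)
  for (s in seq_len(nb)) {
    enc_i <- nb - s + 1L                      # encoder block whose pool is undone
    cin <- ch[enc_i]                          # unpool output channels
    cout <- if (enc_i > 1L) ch[enc_i - 1L] else ch[1L]
    layers <- conv_bn_relu(cin, cout)
    layers <- c(layers, conv_bn_relu(cout, cout))
    layers <- c(layers, list(drop = dropout_new(cfg$dropout)))
    m$dec_stages[[s]] <- list(unpool = unpool_layer_new(), layers = layers)
  }
  m$seg_final <- conv2d_new(ch[1L], 1L, 1L)
  m$seg_sigmoid <- sigmoid_new()
  # classification head
  grid <- c(cfg$input_size[1] %/% 2^nb, cfg$input_size[2] %/% 2^nb)
  m$cls_head <- switch(cfg$variant,
    segnet_mlp = mlp_head_new(cN, cfg),
    segnet_resnet_mlp = mlp_head_new(cN, cfg),
    segnet_resnet_vit = vit_head_new(cN, grid, cfg, use_dist = FALSE),
    segnet_resnet_deit = vit_head_new(cN, grid, cfg, use_dist = TRUE))
  m$sig_cls <- sigmoid_new()
  m$sig_dist <- if (identical(m$cls_head$type, "vit") && m$cls_head$use_dist)
    sigmoid_new()
  class(m) <- "cytomtl_model"
  m
}

# Flat list of every layer that owns parameters, in a fixed order.
collect_layers <- function(model) {
  out <- list()
  add <- function(x) {
    if (inherits(x, "nn_layer")) {
      if (length(x$params)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) for (el in x) add(el)
  }
  add(model$enc_blocks)
  add(model$bridge)
  add(model$dec_stages)
  add(list(model$seg_final))
  add(model$cls_head)
  out
}

#' Number of trainable parameters
#' @param model a model built by [build_model()].
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_layers(model),
             function(l) sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

run_seq <- function(layers, x, training) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

back_seq <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

bottleneck_forward <- function(st, x, training) {
  y <- layer_forward(st$c1, x, training)
  y <- layer_forward(st$b1, y, training)
  y <- layer_forward(st$r1, y, training)
  y <- layer_forward(st$c2, y, training)
  y <- layer_forward(st$b2, y, training)
  y <- layer_forward(st$r2, y, training)
  y <- layer_forward(st$c3, y, training)
  y <- layer_forward(st$b3, y, training)
  layer_forward(st$r_out, y + x, training)
}

bottleneck_backward <- function(st, dy) {
  dsum <- layer_backward(st$r_out, dy)
  d <- layer_backward(st$b3, dsum)
  d <- layer_backward(st$c3, d)
  d <- layer_backward(st$r2, d)
  d <- layer_backward(st$b2, d)
  d <- layer_backward(st$c2, d)
  d <- layer_backward(st$r1, d)
  d <- layer_backward(st$b1, d)
  d <- layer_backward(st$c1, d)
  d + dsum                      # residual shortcut
}

# Global average pool (C,H,W,N) -> (N, C), and its backward.
gap2 <- function(x) {
  d <- dim(x)
  tmp <- array(x, c(d[1], d[2] * d[3], d[4]))
  out <- matrix(0, d[4], d[1])
  for (n in seq_len(d[4])) out[n, ] <- rowMeans(tmp[, , n, drop = FALSE])
  out
}

gap2_backward <- function(dg, dims) {
  # dg is (N, C); every pixel receives dg/(H*W)
  arr <- array(0, dims)
  for (n in seq_len(dims[4])) arr[, , , n] <- dg[n, ] / (dims[2] * dims[3])
  arr
}

patchify <- function(x, p) {
  d <- dim(x)                                # (C, H, W, N)
  Hp <- d[2] %/% p; Wp <- d[3] %/% p
  dim(x) <- c(d[1], p, Hp, p, Wp, d[4])
  y <- aperm(x, c(1, 2, 4, 3, 5, 6))         # (C, p, p, Hp, Wp, N)
  aperm(array(y, c(d[1] * p * p, Hp * Wp, d[4])), c(2, 1, 3))
}

unpatchify <- function(tok, p, dims) {
  Hp <- dims[2] %/% p; Wp <- dims[3] %/% p
  y <- aperm(tok, c(2, 1, 3))                # (C*p*p, T, N)
  dim(y) <- c(dims[1], p, p, Hp, Wp, dims[4])
  x <- aperm(y, c(1, 2, 4, 3, 5, 6))         # (C, p, Hp, p, Wp, N)
  dim(x) <- dims
  x
}

vit_forward <- function(hd, x, training) {
  d <- dim(x); N <- d[4]
  tok <- layer_forward(hd$embed, patchify(x, hd$p), training)   # (Tp, D, N)
  nt <- hd$nt
  z <- array(0, c(hd$Tp + nt, hd$D, N))
  z[1, , ] <- matrix(hd$tokens$params$cls, hd$D, N)
  if (hd$use_dist) z[2, , ] <- matrix(hd$tokens$params$dist, hd$D, N)
  z[(nt + 1):(nt + hd$Tp), , ] <- tok
  z <- z + array(as.vector(hd$tokens$params$pos), dim(z))
  for (bl in hd$blocks) {
    z <- z + layer_forward(bl$attn, layer_forward(bl$ln1, z, training), training)
    h <- layer_forward(bl$ln2, z, training)
    h <- layer_forward(bl$fc1, h, training)
    h <- layer_forward(bl$act, h, training)
    z <- z + layer_forward(bl$fc2, h, training)
  }
  z <- layer_forward(hd$ln_f, z, training)
  h_cls <- layer_forward(hd$drop_cls, t(matrix(z[1, , ], hd$D, N)), training)
  logit_cls <- as.vector(layer_forward(hd$head_cls, h_cls, training))
  logit_dist <- NULL
  if (hd$use_dist) {
    h_dist <- layer_forward(hd$drop_dist, t(matrix(z[2, , ], hd$D, N)), training)
    logit_dist <- as.vector(layer_forward(hd$head_dist, h_dist, training))
  }
  list(logit_cls = logit_cls, logit_dist = logit_dist)
}

vit_backward <- function(hd, dlogit_cls, dlogit_dist, dims) {
  N <- dims[4]
  dz <- array(0, c(hd$Tp + hd$nt, hd$D, N))
  dcls <- layer_backward(hd$head_cls, matrix(dlogit_cls, N, 1L))
  dcls <- layer_backward(hd$drop_cls, dcls)
  dz[1, , ] <- t(dcls)
  if (hd$use_dist && !is.null(dlogit_dist)) {
    ddist <- layer_backward(hd$head_dist, matrix(dlogit_dist, N, 1L))
    ddist <- layer_backward(hd$drop_dist, ddist)
    dz[2, , ] <- t(ddist)
  }
  dz <- layer_backward(hd$ln_f, dz)
  for (bl in rev(hd$blocks)) {
    dh <- layer_backward(bl$fc2, dz)
    dh <- layer_backward(bl$act, dh)
    dh <- layer_backward(bl$fc1, dh)
    dz <- dz + layer_backward(bl$ln2, dh)
    da <- layer_backward(bl$attn, dz)
    dz <- dz + layer_backward(bl$ln1, da)
  }
  # token and positional-embedding gradients
  hd$tokens$grads <- list(
    cls = rowSums(matrix(dz[1, , ], hd$D, N)),
    pos = matrix(rowSums(matrix(dz, length(dz) / N, N)),
                 hd$Tp + hd$nt, hd$D))
  if (hd$use_dist) hd$tokens$grads$dist <- rowSums(matrix(dz[2, , ], hd$D, N))
  nt <- hd$nt
  dtok <- dz[(nt + 1):(nt + hd$Tp), , , drop = FALSE]
  dpat <- layer_backward(hd$embed, dtok)
  unpatchify(dpat, hd$p, dims)
}

mlp_head_forward <- function(hd, x, training) {
  g <- gap2(x)
  h <- layer_forward(hd$fc1, g, training)
  h <- layer_forward(hd$act, h, training)
  h <- layer_forward(hd$drop, h, training)
  logit <- as.vector(layer_forward(hd$fc2, h, training))
  list(logit_cls = logit, logit_dist = NULL)
}

mlp_head_backward <- function(hd, dlogit, dims) {
  d <- layer_backward(hd$fc2, matrix(dlogit, dims[4], 1L))
  d <- layer_backward(hd$drop, d)
  d <- layer_backward(hd$act, d)
  dg <- layer_backward(hd$fc1, d)
  gap2_backward(dg, dims)
}

#' Forward pass
#'
#' Runs a batch through the network and returns both heads: a per-pixel
#' foreground probability map and a per-image class probability. In the
#' full variant the distillation token produces a second probability; the
#' reported `cls_prob` is the sigmoid of the mean of the two logits.
#'
#' @param model a model from [build_model()].
#' @param x numeric array `H x W x C x N` (values in \[0,1\]).
#' @param training logical; enables batch statistics, dropout and caching
#'   for a subsequent [model_backward()].
#' @return list with `mask_prob` (`H x W x N`), `cls_prob`, `cls_token_prob`,
#'   `dist_token_prob` (NULL without a distillation token).
#' @export
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) == 3) dim(x) <- d <- c(d, 1L)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] || d[3] != cfg$input_size[3])
    stop("input dims do not match model config")
  x <- aperm(x, c(3, 1, 2, 4))               # internal channel-first layout
  nb <- length(cfg$channels)
  skips <- vector("list", nb)
  for (i in seq_len(nb)) {
    blk <- model$enc_blocks[[i]]
    x <- run_seq(blk$layers, x, training)
    if (cfg$skip_add) skips[[i]] <- x
    x <- layer_forward(blk$pool, x, training)
  }
  enc_out <- x
  if (!is.null(model$bridge)) {
    x <- run_seq(model$bridge$proj, x, training)
    for (st in model$bridge$stages) x <- bottleneck_forward(st, x, training)
  }
  feat <- x                                  # decoder + classifier input
  model$feat_dims <- dim(feat)
  # segmentation branch
  y <- feat
  for (s in seq_len(nb)) {
    stg <- model$dec_stages[[s]]
    pool <- model$enc_blocks[[nb - s + 1L]]$pool
    stg$unpool$k <- pool$k
    stg$unpool$dims <- pool$dims
    y <- layer_forward(stg$unpool, y, training)
    if (cfg$skip_add) y <- y + skips[[nb - s + 1L]]
    y <- run_seq(stg$layers, y, training)
  }
  logit_map <- layer_forward(model$seg_final, y, training)
  mask_prob <- layer_forward(model$seg_sigmoid, logit_map, training)
  mask_prob <- array(mask_prob, c(d[1], d[2], d[4]))
  # classification branch
  if (identical(model$cls_head$type, "vit")) {
    cl <- vit_forward(model$cls_head, feat, training)
  } else {
    cl <- mlp_head_forward(model$cls_head, feat, training)
  }
  cls_token_prob <- as.vector(layer_forward(model$sig_cls, cl$logit_cls, training))
  dist_token_prob <- NULL
  if (!is.null(cl$logit_dist)) {
    dist_token_prob <- as.vector(layer_forward(model$sig_dist, cl$logit_dist, training))
    cls_prob <- 1 / (1 + exp(-(cl$logit_cls + cl$logit_dist) / 2))
  } else cls_prob <- cls_token_prob
  list(mask_prob = mask_prob, cls_prob = cls_prob,
       cls_token_prob = cls_token_prob, dist_token_prob = dist_token_prob)
}

#' Backward pass
#'
#' Backpropagates gradients of a scalar loss with respect to the forward
#' outputs through the whole network, filling every layer's `$grads`. Must
#' follow a `training = TRUE` forward on the same batch.
#'
#' @param model the model used in the forward pass.
#' @param dmask gradient wrt `mask_prob` (`H x W x N`).
#' @param dcls gradient wrt `cls_token_prob` (length `N`).
#' @param ddist gradient wrt `dist_token_prob`, or NULL.
#' @return invisibly, the gradient with respect to the input batch.
#' @export
model_backward <- function(model, dmask, dcls, ddist = NULL) {
  cfg <- model$config
  nb <- length(cfg$channels)
  d <- c(1L, cfg$input_size[1], cfg$input_size[2],
         length(dmask) %/% (cfg$input_size[1] * cfg$input_size[2]))
  # segmentation branch
  dy <- layer_backward(model$seg_sigmoid, array(dmask, d))
  dy <- layer_backward(model$seg_final, dy)
  dskips <- vector("list", nb)
  for (s in rev(seq_len(nb))) {
    stg <- model$dec_stages[[s]]
    dy <- back_seq(stg$layers, dy)
    if (cfg$skip_add) dskips[[nb - s + 1L]] <- dy
    dy <- layer_backward(stg$unpool, dy)
  }
  dfeat <- dy
  # classification branch
  N <- d[4]
  dlog_cls <- layer_backward(model$sig_cls, dcls)
  if (identical(model$cls_head$type, "vit")) {
    dlog_dist <- if (!is.null(ddist)) layer_backward(model$sig_dist, ddist)
    dfeat <- dfeat + vit_backward(model$cls_head, dlog_cls, dlog_dist,
                                  model$feat_dims)
  } else {
    dfeat <- dfeat + mlp_head_backward(model$cls_head, dlog_cls, model$feat_dims)
  }
  # bridge
  dx <- dfeat
  if (!is.null(model$bridge)) {
    for (st in rev(model$bridge$stages)) dx <- bottleneck_backward(st, dx)
    dx <- back_seq(model$bridge$proj, dx)
  }
  # encoder
  for (i in rev(seq_len(nb))) {
    blk <- model$enc_blocks[[i]]
    dx <- layer_backward(blk$pool, dx)
    if (cfg$skip_add && !is.null(dskips[[i]])) dx <- dx + dskips[[i]]
    dx <- back_seq(blk$layers, dx)
  }
  invisible(aperm(dx, c(2, 3, 1, 4)))        # back to (H, W, C, N)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration, all parameter
#' arrays, and batch-norm running statistics.
#' @param model a built model.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  layers <- collect_layers(model)
  state <- list(config = model$config,
                params = lapply(layers, function(l) l$params),
                bn = lapply(layers, function(l)
                  if (identical(l$type, "bn"))
                    list(mean = l$running_mean, var = l$running_var)))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable checkpoint: ", conditionMessage(e)))
  if (!is.list(state) || is.null(state$config) || is.null(state$params))
    stop("corrupt checkpoint: missing config or parameters")
  model <- build_model(state$config)
  layers <- collect_layers(model)
  if (length(layers) != length(state$params))
    stop("corrupt checkpoint: layer count mismatch")
  for (i in seq_along(layers)) {
    layers[[i]]$params <- state$params[[i]]
    if (identical(layers[[i]]$type, "bn") && !is.null(state$bn[[i]])) {
      layers[[i]]$running_mean <- state$bn[[i]]$mean
      layers[[i]]$running_var <- state$bn[[i]]$var
    }
  }
  model
}

#' Freeze or unfreeze batch-norm statistics
#'
#' With frozen statistics, training-mode forward passes use the running
#' mean/variance as constants (no batch statistics, no running-stat
#' updates), which makes per-sample computations independent of batch
#' composition — the precondition for exact gradient-accumulation
#' equivalence.
#'
#' @param model a built model.
#' @param frozen logical.
#' @export
set_bn_frozen <- function(model, frozen = TRUE) {
  for (l in collect_layers(model))
    if (identical(l$type, "bn")) l$frozen <- frozen
  invisible(model)
}
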