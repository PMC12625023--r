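# Stage-wise forward entry points. These run the same layer objects as
# model_forward() but expose the intermediate contracts — encoder state
# with pooling indices, bridge features, decoder mask, classifier head —
# so each stage can be examined and tested in isolation. Arrays use the
# public (H, W, C, N) orientation.

chw_in <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  aperm(x, c(3, 1, 2, 4))
}
chw_out <- function(x) aperm(x, c(2, 3, 1, 4))

#' Encoder forward pass with preserved pooling indices
#'
#' @param model a built model.
#' @param x image batch `H x W x C x N` (or a single `H x W x C` image).
#' @param training use batch statistics and caching.
#' @return list with `feature_map` (`H' x W' x C' x N`), `pooling_indices`
#'   (one integer array per pooling stage, window argmax in 1..4) and
#'   `skip_features` (pre-pool maps, `H x W x C x N` orientation).
#' @export
encoder_forward <- function(model, x, training = FALSE) {
  z <- chw_in(x)
  nb <- length(model$config$channels)
  skips <- vector("list", nb)
  idx <- vector("list", nb)
  for (i in seq_len(nb)) {
    blk <- model$enc_blocks[[i]]
    z <- run_seq(blk$layers, z, training)
    skips[[i]] <- chw_out(z)
    z <- layer_forward(blk$pool, z, training)
    idx[[i]] <- blk$pool$k
  }
  list(feature_map = chw_out(z), pooling_indices = idx, skip_features = skips)
}

#' Residual bridge forward pass
#'
#' 1x1 projection followed by the bottleneck residual stages; spatial dims
#' are preserved (stride 1 throughout).
#' @param model a built model with a bridge (any variant except
#'   `segnet_mlp`).
#' @param features encoder output, `H' x W' x C' x N`.
#' @param training use batch statistics.
#' @export
bridge_forward <- function(model, features, training = FALSE) {
  if (is.null(model$bridge)) stop("this variant has no bridge")
  z <- run_seq(model$bridge$proj, chw_in(features), training)
  for (st in model$bridge$stages) z <- bottleneck_forward(st, z, training)
  chw_out(z)
}

#' Decoder forward pass (index-guided unpooling)
#'
#' Uses the pooling indices recorded by the most recent encoder pass on
#' `model` (via [encoder_forward()] or [model_forward()]).
#' @param model a built model whose encoder has been run.
#' @param features bridge (or encoder) output, `H' x W' x C' x N`.
#' @param training use batch statistics and dropout.
#' @return mask probability array `H x W x N`.
#' @export
decoder_forward <- function(model, features, training = FALSE) {
  cfg <- model$config
  nb <- length(cfg$channels)
  y <- chw_in(features)
  for (s in seq_len(nb)) {
    stg <- model$dec_stages[[s]]
    pool <- model$enc_blocks[[nb - s + 1L]]$pool
    if (is.null(pool$k)) stop("run the encoder before the decoder")
    stg$unpool$k <- pool$k
    stg$unpool$dims <- pool$dims
    y <- layer_forward(stg$unpool, y, training)
    y <- run_seq(stg$layers, y, training)
  }
  lg <- layer_forward(model$seg_final, y, training)
  pr <- layer_forward(model$seg_sigmoid, lg, training)
  array(pr, dim(pr)[c(2, 3, 4)])
}

#' Classification head forward pass
#'
#' @param model a built model.
#' @param features the head's input feature map (`H' x W' x C' x N`):
#'   bridge output, or encoder output for `segnet_mlp`.
#' @param training enable dropout.
#' @return list with `cls_prob` and (full variant) `dist_prob`.
#' @export
deit_head_forward <- function(model, features, training = FALSE) {
  z <- chw_in(features)
  model$feat_dims <- dim(z)
  if (identical(model$cls_head$type, "vit")) {
    cl <- vit_forward(model$cls_head, z, training)
  } else {
    cl <- mlp_head_forward(model$cls_head, z, training)
  }
  list(cls_prob = 1 / (1 + exp(-cl$logit_cls)),
       dist_prob = if (!is.null(cl$logit_dist)) 1 / (1 + exp(-cl$logit_dist)))
}
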