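# Training regimen: Adam with L2 weight decay, cosine-annealed learning
# rate, micro-batch gradient accumulation to a larger effective batch,
# dynamic paired augmentation, early stopping on validation loss with
# best-weight restoration.

#' Training configuration
#'
#' Defaults follow the study regimen: Adam at 1e-4 with weight decay 1e-5,
#' batch 8 with 2-step gradient accumulation (effective batch 16), up to
#' 30 epochs, early stopping patience 10 on validation loss, cosine
#' annealing to a zero floor.
#'
#' @param learning_rate initial Adam learning rate.
#' @param weight_decay L2 coefficient added to gradients.
#' @param batch_size micro-batch size.
#' @param grad_accumulation_steps micro-batches accumulated per optimizer
#'   step.
#' @param max_epochs epoch budget (also the cosine period `t_max`).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param floor_lr cosine annealing floor.
#' @param loss_weights a [loss_weights()].
#' @param augment apply random paired augmentation to training batches.
#' @param seed drives weight init (if the model config has none), shuffling
#'   and augmentation.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         batch_size = 8L, grad_accumulation_steps = 2L,
                         max_epochs = 30L, early_stop_patience = 10L,
                         floor_lr = 0, loss_weights = NULL,
                         augment = TRUE, seed = 1L) {
  if (is.null(loss_weights)) loss_weights <- cytomtl::loss_weights()
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 grad_accumulation_steps = as.integer(grad_accumulation_steps),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 floor_lr = floor_lr, loss_weights = loss_weights,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `floor + (initial - floor) * (1 + cos(pi * epoch / t_max)) / 2`:
#' the initial rate at epoch 0, the floor at epoch `t_max`.
#'
#' @param epoch current epoch, `0 <= epoch <= t_max`.
#' @param initial_lr,floor_lr rate endpoints.
#' @param t_max annealing period in epochs.
#' @export
cosine_lr <- function(epoch, initial_lr, t_max, floor_lr = 0) {
  if (t_max <= 0) stop("t_max must be positive")
  stopifnot(epoch >= 0, epoch <= t_max)
  floor_lr + (initial_lr - floor_lr) * (1 + cos(pi * epoch / t_max)) / 2
}

# -- Adam -------------------------------------------------------------------

adam_state_new <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, state, grads, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * l$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  state
}

zero_grad_acc <- function(layers) {
  lapply(layers, function(l) lapply(l$params, function(p) NULL))
}

accumulate_grads <- function(acc, layers, scale) {
  for (i in seq_along(layers)) {
    g <- layers[[i]]$grads
    for (nm in names(layers[[i]]$params)) {
      if (is.null(g[[nm]])) next
      acc[[i]][[nm]] <- if (is.null(acc[[i]][[nm]])) g[[nm]] * scale
                        else acc[[i]][[nm]] + g[[nm]] * scale
    }
  }
  acc
}

# Forward + loss + backward on one stacked micro-batch; fills layer grads.
train_step_grads <- function(model, batch, weights) {
  out <- model_forward(model, batch$x, training = TRUE)
  tl <- total_loss(out$mask_prob, batch$masks, out$cls_token_prob,
                   batch$labels, weights, dist_prob = out$dist_token_prob,
                   grad = TRUE)
  model_backward(model, tl$dmask, tl$dcls, tl$ddist)
  list(loss = tl$value, out = out)
}

epoch_loss <- function(model, pairs, weights, batch_size = 8L) {
  tot <- 0; n <- 0
  for (b in batch_indices(length(pairs), batch_size, shuffle = FALSE)) {
    st <- stack_pairs(pairs[b])
    out <- model_forward(model, st$x, training = FALSE)
    tot <- tot + total_loss(out$mask_prob, st$masks, out$cls_token_prob,
                            st$labels, weights, out$dist_token_prob) * length(b)
    n <- n + length(b)
  }
  tot / n
}

batch_indices <- function(n, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

snapshot_params <- function(layers)
  lapply(layers, function(l) list(params = l$params,
                                  bn = if (identical(l$type, "bn"))
                                    list(mean = l$running_mean, var = l$running_var)))

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$bn)) {
      layers[[i]]$running_mean <- snap[[i]]$bn$mean
      layers[[i]]$running_var <- snap[[i]]$bn$var
    }
  }
}

#' Train a model
#'
#' Per epoch: shuffled micro-batches, gradients accumulated over
#' `grad_accumulation_steps` micro-batches per Adam step, optional dynamic
#' paired augmentation, cosine-annealed learning rate, validation loss
#' computed in inference mode; early stopping with best-weight restoration.
#'
#' @param model a [build_model()] output (trained in place and returned).
#' @param train_pairs,val_pairs disjoint lists of [image_mask_pair()].
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (data.frame epoch/lr/train_loss/
#'   val_loss/val_dice), `best_epoch`, `best_val_loss`.
#' @export
train <- function(model, train_pairs, val_pairs, config = train_config(),
                  verbose = FALSE) {
  if (length(train_pairs) == 0) stop("empty training set")
  if (length(val_pairs) == 0) stop("empty validation set")
  if (length(intersect(vapply(train_pairs, `[[`, "", "sample_id"),
                       vapply(val_pairs, `[[`, "", "sample_id"))) > 0)
    warning("train and validation sets share sample ids")
  layers <- collect_layers(model)
  state <- adam_state_new(layers)
  w <- config$loss_weights
  history <- data.frame()
  best_val <- Inf; best_snap <- snapshot_params(layers); best_epoch <- 0L
  bad_epochs <- 0L; t_adam <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- cosine_lr(epoch - 1L, config$learning_rate, config$max_epochs,
                      config$floor_lr)
      batches <- batch_indices(length(train_pairs), config$batch_size)
      acc <- zero_grad_acc(layers)
      n_acc <- 0L
      train_loss_sum <- 0; train_n <- 0
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        pairs <- train_pairs[b]
        if (config$augment)
          pairs <- lapply(pairs, function(p)
            augment_pair(p, seed = sample.int(.Machine$integer.max, 1)))
        st <- stack_pairs(pairs)
        res <- train_step_grads(model, st, w)
        acc <- accumulate_grads(acc, layers, 1 / config$grad_accumulation_steps)
        n_acc <- n_acc + 1L
        train_loss_sum <- train_loss_sum + res$loss * length(b)
        train_n <- train_n + length(b)
        if (n_acc == config$grad_accumulation_steps || bi == length(batches)) {
          # a short trailing group still averages over the accumulated count
          if (n_acc < config$grad_accumulation_steps)
            acc <- rapply(acc, function(g)
              g * config$grad_accumulation_steps / n_acc, how = "replace")
          t_adam <- t_adam + 1L
          state <- adam_step(layers, state, acc, lr, t_adam, config$weight_decay)
          acc <- zero_grad_acc(layers)
          n_acc <- 0L
        }
      }
      val_loss <- epoch_loss(model, val_pairs, w, config$batch_size)
      val_dice <- evaluate_dice(model, val_pairs, config$batch_size)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = train_loss_sum / train_n,
        val_loss = val_loss, val_dice = val_dice))
      if (verbose)
        message(sprintf("epoch %3d lr %.2e train %.4f val %.4f dice %.4f",
                        epoch, lr, train_loss_sum / train_n, val_loss, val_dice))
      if (val_loss < best_val) {
        best_val <- val_loss; best_snap <- snapshot_params(layers)
        best_epoch <- epoch; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > config$early_stop_patience) break
      }
    }
  })
  restore_params(layers, best_snap)
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_loss = best_val)
}

# Pixel-level Dice of thresholded predictions over a pair list.
evaluate_dice <- function(model, pairs, batch_size = 8L) {
  tp <- 0; fp <- 0; fn <- 0
  for (b in batch_indices(length(pairs), batch_size, shuffle = FALSE)) {
    st <- stack_pairs(pairs[b])
    out <- model_forward(model, st$x, training = FALSE)
    pred <- out$mask_prob >= 0.5
    tp <- tp + sum(pred & st$masks == 1)
    fp <- fp + sum(pred & st$masks == 0)
    fn <- fn + sum(!pred & st$masks == 1)
  }
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# Inference on a list of pairs; returns per-sample outputs. `model` may
# also be a plain function(x_batch) returning list(mask_prob, cls_prob),
# which lets reference predictors stand in for a network in tests.
predict_pairs <- function(model, pairs, batch_size = 8L) {
  preds <- vector("list", length(pairs))
  for (b in batch_indices(length(pairs), batch_size, shuffle = FALSE)) {
    st <- stack_pairs(pairs[b])
    out <- if (is.function(model)) model(st$x)
           else model_forward(model, st$x, training = FALSE)
    for (j in seq_along(b)) {
      preds[[b[j]]] <- list(
        sample_id = st$sample_ids[j],
        mask_prob = out$mask_prob[, , j],
        cls_prob = out$cls_prob[j],
        dist_prob = if (!is.null(out$dist_token_prob)) out$dist_token_prob[j])
    }
  }
  preds
}

#' Predict masks and labels
#'
#' Single forward pass per batch yielding both heads; masks and labels are
#' thresholded at 0.5. Optionally writes predicted-mask PNGs and a CSV of
#' `(sample_id, class_probability, label)`.
#'
#' @param model a built model or a checkpoint path.
#' @param pairs list of [image_mask_pair()] (masks may be all-zero for
#'   unlabeled input).
#' @param out_dir optional output directory for PNGs + CSV.
#' @param batch_size forward-pass batch size.
#' @return list per sample: `sample_id`, `mask_prob`, `mask` (binary),
#'   `cls_prob`, `label`.
#' @export
predict_model <- function(model, pairs, out_dir = NULL, batch_size = 8L) {
  if (is.character(model)) model <- load_checkpoint(model)
  preds <- predict_pairs(model, pairs, batch_size)
  res <- lapply(preds, function(p)
    list(sample_id = p$sample_id, mask_prob = p$mask_prob,
         mask = (p$mask_prob >= 0.5) * 1L, cls_prob = p$cls_prob,
         label = as.integer(p$cls_prob >= 0.5)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in res)
      png::writePNG(p$mask * 1.0, file.path(out_dir, paste0(p$sample_id, "_pred.png")))
    utils::write.csv(data.frame(
      sample_id = vapply(res, `[[`, "", "sample_id"),
      class_probability = vapply(res, `[[`, 0, "cls_prob"),
      label = vapply(res, `[[`, 0L, "label")),
      file.path(out_dir, "predictions.csv"), row.names = FALSE)
  }
  res
}

#' Ablation study runner
#'
#' Trains each architecture variant identically on the same seeded
#' synthetic fixtures and reports image- and pixel-level metrics plus
#' parameter counts. Nothing is asserted about ordering; the table is
#' reported as computed.
#'
#' @param variants character vector of model variants (at least 2).
#' @param synth_cfg a [synth_config()] defining the fixture data.
#' @param train_cfg a [train_config()].
#' @param model_args extra arguments passed to [model_config_tiny()].
#' @return data.frame, one row per variant.
#' @export
run_ablation <- function(variants, synth_cfg, train_cfg,
                         model_args = list()) {
  if (length(variants) < 2) stop("need at least 2 variants")
  pairs <- generate_dataset(synth_cfg)
  sp <- stratified_split(vapply(pairs, `[[`, 0, "label"), 0.8, train_cfg$seed)
  rows <- lapply(variants, function(v) {
    args <- c(model_args,
              list(variant = v, input_size = c(synth_cfg$image_size, 3L),
                   seed = train_cfg$seed))
    args <- args[!duplicated(names(args), fromLast = TRUE)]
    model <- build_model(do.call(model_config_tiny, args))
    fit <- train(model, pairs[sp$train], pairs[sp$validation], train_cfg)
    img <- evaluate_model(fit$model, pairs[sp$validation], "image")
    pix <- evaluate_model(fit$model, pairs[sp$validation], "pixel")
    data.frame(variant = v, parameters = count_parameters(model),
               accuracy = img$accuracy, precision = img$precision,
               recall = img$recall, f1 = img$f1,
               pixel_dice = pix$dice, pixel_iou = pix$iou)
  })
  do.call(rbind, rows)
}
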