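# Scaled-down capability studies on synthetic fixtures. These are the
# package's evidence that (a) the full multi-task network can fit lesion
# masks at all (overfit study) and (b) synthetic fixtures carry enough
# signal for a fixture-trained model to generalize to held-out draws of
# the same generator (held-out study). Problem sizes are chosen for
# single-CPU minutes; see the methods vignette for the rationale.

derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 97L + k) %% 2147483646L + 1L)

#' Overfit study: tiny network, eight fixtures
#'
#' Trains the tiny full-variant network (indices-only decoder) on 8
#' synthetic 64x64 images for 100 epochs (Adam 3e-3, micro-batch 2, no
#' augmentation, cosine annealing) and reports the training-set pixel
#' Dice. A healthy implementation memorizes the 8 masks almost perfectly.
#'
#' @param seed integer; drives data generation, initialization and
#'   shuffling.
#' @param epochs epoch budget.
#' @return list with `train_dice`, `history`, `model`.
#' @export
fixture_overfit_study <- function(seed = 1L, epochs = 100L) {
  sc <- synth_config(n_images = 8, image_size = c(64L, 64L),
                     lesion_probability = 0.75, seed = derive_seed(seed, 1L))
  pairs <- generate_dataset(sc)
  model <- build_model(model_config_tiny(variant = "segnet_resnet_deit",
                                         seed = derive_seed(seed, 2L)))
  tc <- train_config(learning_rate = 3e-3, batch_size = 2L,
                     grad_accumulation_steps = 1L, max_epochs = epochs,
                     early_stop_patience = epochs, augment = FALSE,
                     seed = derive_seed(seed, 3L))
  # validation set == training set by design: the study probes memorization
  fit <- suppressWarnings(train(model, pairs, pairs, tc))
  list(train_dice = evaluate_dice(fit$model, pairs), history = fit$history,
       model = fit$model)
}

#' Held-out study: generalization within the generator's distribution
#'
#' Generates 32 synthetic 64x64 images, splits them 24/8 with
#' stratification, trains the tiny full-variant network with the additive
#' encoder-decoder skip path enabled, and reports pixel-level metrics on
#' the 8 held-out images.
#'
#' @param seed integer; drives every random draw.
#' @param epochs epoch budget.
#' @return list with `heldout_dice`, `heldout_iou`, `image_report`,
#'   `pixel_report`, `model`.
#' @export
fixture_holdout_study <- function(seed = 1L, epochs = 60L) {
  sc <- synth_config(n_images = 32, image_size = c(64L, 64L),
                     lesion_probability = 0.5, seed = derive_seed(seed, 4L))
  pairs <- generate_dataset(sc)
  labs <- vapply(pairs, `[[`, 0, "label")
  sp <- stratified_split(labs, 0.75, seed = derive_seed(seed, 5L))
  model <- build_model(model_config_tiny(variant = "segnet_resnet_deit",
                                         skip_add = TRUE,
                                         seed = derive_seed(seed, 6L)))
  tc <- train_config(learning_rate = 3e-3, batch_size = 2L,
                     grad_accumulation_steps = 1L, max_epochs = epochs,
                     early_stop_patience = epochs, augment = FALSE,
                     seed = derive_seed(seed, 7L))
  fit <- train(model, pairs[sp$train], pairs[sp$validation], tc)
  pix <- evaluate_model(fit$model, pairs[sp$validation], "pixel")
  img <- evaluate_model(fit$model, pairs[sp$validation], "image")
  list(heldout_dice = pix$dice, heldout_iou = pix$iou,
       pixel_report = pix, image_report = img, model = fit$model)
}
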