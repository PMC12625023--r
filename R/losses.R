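# Composite multi-task loss: the segmentation branch combines pixel-wise
# binary cross-entropy with soft Dice, the classification branch is scalar
# BCE, and the total is L_seg + alpha * L_cls. Every loss returns an
# analytic gradient alongside its value so the training loop needs no
# numeric differentiation.

#' Loss weights
#'
#' @param lambda1 weight of the pixel BCE term (default 0.6, the grid-search
#'   optimum).
#' @param lambda2 weight of the soft-Dice term (default 0.4);
#'   `lambda1 + lambda2` is 1 in every searched configuration.
#' @param alpha weight of the classification loss in the total (default 1).
#' @param epsilon Dice smoothing constant guarding empty masks.
#' @param eps_clip probability clamp applied before logarithms.
#' @export
loss_weights <- function(lambda1 = 0.6, lambda2 = 0.4, alpha = 1,
                         epsilon = 1e-6, eps_clip = 1e-7) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, alpha >= 0, epsilon > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
                 epsilon = epsilon, eps_clip = eps_clip),
            class = "loss_weights")
}

#' Pixel-wise binary cross-entropy
#'
#' Mean of `-[g log p + (1-g) log(1-p)]` over all pixels; probabilities are
#' clamped to `[eps_clip, 1-eps_clip]` so exact 0/1 predictions never
#' produce infinite loss.
#'
#' @param p probability map (any shape).
#' @param g binary ground-truth map, same shape.
#' @param eps_clip clamp bound.
#' @param grad also return the gradient with respect to `p`.
#' @return the scalar loss, or (with `grad`) a list `value`, `grad`.
#' @export
bce_pixel_loss <- function(p, g, eps_clip = 1e-7, grad = FALSE) {
  if (length(p) != length(g)) stop("p and g differ in size")
  pc <- clamp01(p, eps_clip)
  n <- length(p)
  val <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  if (!grad) return(val)
  list(value = val, grad = (pc - g) / (pc * (1 - pc)) / n)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)`, computed on raw
#' probabilities (no thresholding) per sample and averaged over the batch.
#' The smoothing constant makes the empty-vs-empty case an exact 0.
#'
#' @param p probability map; `H x W` or `H x W x N`.
#' @param g binary map of the same shape.
#' @param epsilon smoothing constant.
#' @param grad also return the gradient with respect to `p`.
#' @export
dice_loss <- function(p, g, epsilon = 1e-6, grad = FALSE) {
  if (length(p) != length(g)) stop("p and g differ in size")
  d <- dim(p)
  N <- if (!is.null(d) && length(d) == 3) d[3] else 1L
  pm <- matrix(p, ncol = N)
  gm <- matrix(g, ncol = N)
  inter <- colSums(pm * gm)
  sp <- colSums(pm); sg <- colSums(gm)
  denom <- sp + sg + epsilon
  num <- 2 * inter + epsilon
  val <- mean(1 - num / denom)
  if (!grad) return(val)
  # d/dp_i of -(2 sum(pg)+eps)/(sp+sg+eps), per sample, averaged over batch
  gmat <- -(sweep(2 * gm, 2, denom, `*`) - matrix(num, nrow(gm), N, byrow = TRUE)) /
    matrix(denom^2, nrow(gm), N, byrow = TRUE) / N
  gr <- gmat
  if (!is.null(d)) dim(gr) <- d
  list(value = val, grad = gr)
}

#' Segmentation loss
#'
#' `lambda1 * BCE + lambda2 * Dice`.
#' @param p,g probability and ground-truth maps.
#' @param weights a [loss_weights()].
#' @param grad also return the gradient with respect to `p`.
#' @export
seg_loss <- function(p, g, weights = loss_weights(), grad = FALSE) {
  if (!grad)
    return(weights$lambda1 * bce_pixel_loss(p, g, weights$eps_clip) +
           weights$lambda2 * dice_loss(p, g, weights$epsilon))
  b <- bce_pixel_loss(p, g, weights$eps_clip, grad = TRUE)
  dd <- dice_loss(p, g, weights$epsilon, grad = TRUE)
  list(value = weights$lambda1 * b$value + weights$lambda2 * dd$value,
       grad = weights$lambda1 * b$grad + weights$lambda2 * dd$grad)
}

#' Classification loss
#'
#' Scalar binary cross-entropy between predicted probability and label;
#' vectorized over a batch (mean).
#' @param y_hat predicted probabilities.
#' @param y binary labels.
#' @param eps_clip clamp bound.
#' @param grad also return the gradient with respect to `y_hat`.
#' @export
cls_loss <- function(y_hat, y, eps_clip = 1e-7, grad = FALSE) {
  bce_pixel_loss(y_hat, y, eps_clip, grad)
}

#' Total multi-task loss
#'
#' `L_seg + alpha * L_cls`. When a distillation-token probability is given
#' it is supervised by the same label and its BCE is averaged with the
#' class-token BCE inside the classification term.
#'
#' @param mask_prob,mask predicted probability map and binary ground truth.
#' @param cls_prob,label predicted class probability(ies) and label(s).
#' @param weights a [loss_weights()].
#' @param dist_prob optional distillation-token probability(ies).
#' @param grad also return gradients wrt `mask_prob`, `cls_prob`,
#'   `dist_prob`.
#' @export
total_loss <- function(mask_prob, mask, cls_prob, label,
                       weights = loss_weights(), dist_prob = NULL,
                       grad = FALSE) {
  if (!grad) {
    cl <- cls_loss(cls_prob, label, weights$eps_clip)
    if (!is.null(dist_prob))
      cl <- (cl + cls_loss(dist_prob, label, weights$eps_clip)) / 2
    return(seg_loss(mask_prob, mask, weights) + weights$alpha * cl)
  }
  sg <- seg_loss(mask_prob, mask, weights, grad = TRUE)
  cg <- cls_loss(cls_prob, label, weights$eps_clip, grad = TRUE)
  if (!is.null(dist_prob)) {
    dg <- cls_loss(dist_prob, label, weights$eps_clip, grad = TRUE)
    value <- sg$value + weights$alpha * (cg$value + dg$value) / 2
    list(value = value, dmask = sg$grad,
         dcls = weights$alpha * cg$grad / 2,
         ddist = weights$alpha * dg$grad / 2)
  } else {
    list(value = sg$value + weights$alpha * cg$value, dmask = sg$grad,
         dcls = weights$alpha * cg$grad, ddist = NULL)
  }
}

#' Grid search over loss weights
#'
#' Evaluates a validation scorer on every candidate `(lambda1, lambda2,
#' alpha)` and returns the argmax. Ties are broken towards smaller `alpha`,
#' then larger `lambda1`.
#'
#' @param candidates data.frame with columns `lambda1`, `lambda2`, `alpha`;
#'   defaults to the searched grid (`lambda1 + lambda2 = 1`,
#'   `alpha` in 0.5/1/1.5/2).
#' @param scorer function(weights) returning a scalar validation metric
#'   (larger is better), e.g. validation Dice.
#' @return the winning [loss_weights()], with the full scored grid attached
#'   as attribute `"grid"`.
#' @export
grid_search_weights <- function(scorer, candidates = default_weight_grid()) {
  if (NROW(candidates) == 0) stop("empty candidate grid")
  if (any(abs(candidates$lambda1 + candidates$lambda2 - 1) > 1e-9))
    stop("candidates must satisfy lambda1 + lambda2 == 1")
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    w <- loss_weights(candidates$lambda1[i], candidates$lambda2[i],
                      candidates$alpha[i])
    as.numeric(scorer(w))
  }, numeric(1))
  ord <- order(-scores, candidates$alpha, -candidates$lambda1)
  best <- candidates[ord[1], ]
  out <- loss_weights(best$lambda1, best$lambda2, best$alpha)
  attr(out, "grid") <- cbind(candidates, score = scores)
  out
}

#' @rdname grid_search_weights
#' @export
default_weight_grid <- function() {
  g <- expand.grid(lambda1 = c(0.2, 0.4, 0.5, 0.6, 0.8),
                   alpha = c(0.5, 1, 1.5, 2), KEEP.OUT.ATTRS = FALSE)
  data.frame(lambda1 = g$lambda1, lambda2 = 1 - g$lambda1, alpha = g$alpha)
}
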