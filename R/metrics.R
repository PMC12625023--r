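# Confusion-count algebra and the derived evaluation metrics (accuracy,
# precision, recall, F1, Dice, IoU), ROC/AUC with tie grouping, and model
# evaluation at pixel and image level. On binary counts Dice equals F1
# (2TP/(2TP+FP+FN)) and Dice = 2*IoU/(1+IoU); both identities are exact.

#' Confusion counts
#' @param tp,tn,fp,fn non-negative integers.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tabulate confusion counts from binary arrays
#' @param predicted,truth binary arrays of identical shape.
#' @export
count_confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("dimension mismatch")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("inputs must be binary")
  p <- as.vector(predicted); g <- as.vector(truth)
  confusion_counts(tp = sum(p == 1 & g == 1), tn = sum(p == 0 & g == 0),
                   fp = sum(p == 1 & g == 0), fn = sum(p == 0 & g == 1))
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, returning 0 by convention")
    return(0)
  }
  num / den
}

#' Classification and overlap metrics from confusion counts
#'
#' Zero denominators yield 0 with a warning (documented convention).
#' @param c a [confusion_counts()].
#' @name metrics
#' @export
accuracy <- function(c) safe_ratio(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy")

#' @rdname metrics
#' @export
precision <- function(c) safe_ratio(c$tp, c$tp + c$fp, "precision")

#' @rdname metrics
#' @export
recall <- function(c) safe_ratio(c$tp, c$tp + c$fn, "recall")

#' @rdname metrics
#' @export
f1_score <- function(c) safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "f1")

#' @rdname metrics
#' @export
dice_coefficient <- function(c) safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "dice")

#' @rdname metrics
#' @export
iou <- function(c) safe_ratio(c$tp, c$tp + c$fp + c$fn, "iou")

#' Full metric report from counts
#' @param counts a [confusion_counts()].
#' @param auc optional AUC to attach.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(counts, auc = NA_real_) {
  structure(list(accuracy = accuracy(counts), precision = precision(counts),
                 recall = recall(counts), f1 = f1_score(counts),
                 dice = dice_coefficient(counts), iou = iou(counts),
                 auc = auc, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x[c("accuracy", "precision", "recall", "f1", "dice", "iou", "auc")])
  cat(paste(sprintf("%-9s %.4f", names(v), round_half_up(v, 4)), collapse = "\n"), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (equal scores grouped), returns
#' the FPR/TPR points and the trapezoidal AUC. Requires both classes.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels.
#' @return list `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at the end of each distinct-score block
  blocks <- rle(s)
  ends <- cumsum(blocks$lengths)
  ctp <- cumsum(y)[ends]; cfp <- cumsum(1 - y)[ends]
  tpr <- c(0, ctp / n1); fpr <- c(0, cfp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, blocks$values), auc = auc)
}

#' Evaluate a model on a dataset
#'
#' Runs inference-mode forward passes and tabulates confusion counts either
#' over all mask pixels (`mode = "pixel"`) or over image-level predictions
#' (`mode = "image"`), both at threshold 0.5. AUC is computed from the raw
#' probabilities.
#'
#' @param model a built (or trained) model.
#' @param dataset non-empty list of [image_mask_pair()] objects matching
#'   the model's input size.
#' @param mode `"pixel"` or `"image"`.
#' @param batch_size forward-pass batch size.
#' @return a [metric_report()].
#' @export
evaluate_model <- function(model, dataset, mode = c("pixel", "image"),
                           batch_size = 8L) {
  mode <- match.arg(mode)
  if (length(dataset) == 0) stop("empty dataset")
  preds <- predict_pairs(model, dataset, batch_size)
  if (mode == "pixel") {
    pred <- unlist(lapply(preds, function(p) as.vector(p$mask_prob >= 0.5) * 1))
    truth <- unlist(lapply(dataset, function(p) as.vector(p$mask)))
    scores <- unlist(lapply(preds, function(p) as.vector(p$mask_prob)))
  } else {
    pred <- vapply(preds, function(p) (p$cls_prob >= 0.5) * 1, numeric(1))
    truth <- vapply(dataset, function(p) p$label, numeric(1))
    scores <- vapply(preds, function(p) p$cls_prob, numeric(1))
  }
  auc <- if (length(unique(truth)) == 2) roc_curve(scores, truth)$auc else NA_real_
  metric_report(count_confusion(pred, truth), auc = auc)
}

#' Table of metrics from a counts table
#'
#' Reproduces a comparison table from per-model confusion counts: input a
#' data.frame with columns `model`, `tp`, `tn`, `fp`, `fn`; output one row
#' per model with all six metrics (4-decimal half-up rounding applied when
#' `digits` is given).
#'
#' @param counts_df data.frame of counts.
#' @param digits optional rounding digits for display.
#' @export
metrics_from_counts <- function(counts_df, digits = NULL) {
  need <- c("model", "tp", "tn", "fp", "fn")
  if (!all(need %in% names(counts_df))) stop("need columns ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(counts_df)), function(i) {
    cc <- confusion_counts(counts_df$tp[i], counts_df$tn[i],
                           counts_df$fp[i], counts_df$fn[i])
    r <- metric_report(cc)
    data.frame(model = counts_df$model[i], accuracy = r$accuracy,
               precision = r$precision, recall = r$recall, f1 = r$f1,
               iou = r$iou, dice = r$dice)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits))
    out[-1] <- lapply(out[-1], round_half_up, digits = digits)
  out
}
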