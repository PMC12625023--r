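---
title: "Multi-task cytology image analysis: model, losses, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task cytology image analysis: model, losses, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomtl)
```

## The problem

Screening for cervical cancer rests on bright-field microscopy of Pap
smear slides. Two questions are asked of every scan: *where* are the
abnormal epithelial regions (pixel-wise segmentation), and *does this
image contain any abnormality at all* (binary classification). The two
tasks share almost all of their visual evidence, which motivates a
single network with a shared encoder and two heads, trained jointly.

`cytomtl` implements such a hybrid network natively in R — the forward
pass, the backward pass, and the optimizer are all written against base
R arrays and BLAS — together with the full preprocessing pipeline, the
composite loss, an evaluation suite built on confusion-count algebra,
and a synthetic image generator that makes every component testable
without any external dataset.

## Architecture

The network has four parts:

1. **Convolutional encoder with pooling indices.** Three blocks of
   (3×3 convolution → batch norm → ReLU) × 2 followed by 2×2 max
   pooling. Each pooling layer records the argmax position of every
   window (ties broken by first occurrence in row-major order, for
   determinism). Three poolings take a 256×256 input to a 32×32 map
   (64×64 to 8×8 in the test-scale configuration).
2. **Bottleneck residual bridge.** A 1×1 projection followed by
   bottleneck residual stages (1×1 reduce → 3×3 → 1×1 expand, each
   convolution with batch norm, shortcut added before the final ReLU).
   Stride is 1 throughout, so spatial dimensions are preserved. Zeroing
   the residual branch makes each stage an exact identity — a property
   the test-suite checks. The bridge deepens features for both heads
   without the cost of a full 50-layer backbone at 32×32 resolution;
   the number of stages is a configuration field.
3. **Index-guided unpooling decoder (segmentation head).** Mirrors the
   encoder: each stage unpools with the matching encoder indices —
   placing every value exactly where its activation came from, zeros
   elsewhere — then refines with two conv/BN/ReLU layers and dropout. A
   final 1×1 convolution and sigmoid yield a per-pixel foreground
   probability at the input resolution. Optionally (`skip_add`), the
   encoder's pre-pool feature maps are added after each unpooling; the
   indices always flow regardless.
4. **Transformer classification head.** The bridge output is cut into
   non-overlapping patches (default 2×2), linearly embedded, and
   prepended with a learnable class token and — in the full variant — a
   distillation token; learnable positional embeddings are added. The
   sequence passes through pre-norm transformer blocks (multi-head
   self-attention and a GELU MLP, each with a residual connection), and
   each special token feeds its own linear head and sigmoid.

The distillation token follows the data-efficient transformer recipe.
No teacher network is available here, so by default both tokens are
supervised by the ground-truth label and their logits are averaged at
inference; a teacher hook would slot into the same place. This is the
hard-distillation fallback; the token keeps the architecture faithful
and lets a teacher be added without structural change.

Four ablation variants are constructible through one configuration
switch: encoder + MLP head (no bridge), bridge + MLP head, bridge +
transformer head with class token only, and the full model with both
tokens.

### Wiring choices

Two points were genuinely open and were resolved as follows. First, the
bridge sits between encoder and decoder, and the decoder consumes the
bridge output; skip information reaches the decoder through the pooling
indices (optionally also through additive pre-pool maps). Second, the
input is 3-channel 256×256 (the training configuration), not the
224×224 greyscale of the generic encoder-decoder background; the
channel widths double per block.

All convolution and linear weights use He initialization; token and
positional embeddings are drawn at σ = 0.02. A configuration seed makes
two builds bit-identical.

## Losses

With $p_i$ the predicted foreground probability at pixel $i$ and $g_i$
the binary ground truth:

* Pixel BCE: $\mathcal{L}_{BCE} = -\tfrac1N \sum_i [g_i \log p_i +
  (1-g_i)\log(1-p_i)]$, probabilities clamped to
  $[10^{-7}, 1-10^{-7}]$ before the logarithms.
* Soft Dice: $\mathcal{L}_{DICE} = 1 - \frac{2\sum_i p_i g_i +
  \epsilon}{\sum_i p_i + \sum_i g_i + \epsilon}$ with $\epsilon =
  10^{-6}$, computed on raw probabilities (no thresholding inside the
  loss, which keeps it differentiable) per sample and averaged over the
  batch. The smoothing constant makes the empty-vs-empty case an exact
  zero.
* Segmentation loss: $\lambda_1 \mathcal{L}_{BCE} + \lambda_2
  \mathcal{L}_{DICE}$, defaults $\lambda_1 = 0.6$, $\lambda_2 = 0.4$.
* Classification BCE on the class probability; when the distillation
  token is active its BCE (against the same label) is averaged into the
  classification term.
* Total: $\mathcal{L}_{seg} + \alpha\,\mathcal{L}_{cls}$, default
  $\alpha = 1$.

The defaults are the optimum of a grid search over
$\lambda_1 + \lambda_2 = 1$ and $\alpha \in \{0.5, 1, 1.5, 2\}$;
`grid_search_weights()` reruns that search against any validation
scorer (default metric: validation Dice) and breaks ties toward smaller
$\alpha$, then larger $\lambda_1$. The $\lambda$ grid points are
{0.2, 0.4, 0.5, 0.6, 0.8} — the constraint is stated, the exact points
are a package choice.

Every loss returns its analytic gradient next to its value; the
test-suite checks both against central finite differences, and a
whole-model finite-difference sweep covers every layer type.

## Preprocessing pipeline

* **Normalization** is per-channel min-max to [0, 1], applied per image
  (per-image statistics compensate illumination and staining variation
  between slides). A constant channel maps to all zeros rather than
  dividing by zero.
* **Labels** derive from masks: positive iff any foreground pixel.
* **Resizing** is bilinear for images and nearest-neighbour for masks
  (so masks stay binary), and the label is re-derived afterwards — a
  one-pixel lesion can vanish under nearest-neighbour downscaling, and
  the label must follow the mask it ships with.
* **Patch grids** use 0-based `(row, col)` origins and half-open
  windows; origins advance by `stride`, and the final origin per axis
  is clamped to `dim − patch_size`, so margins are always covered
  (brute-force verified in tests). Patch size and stride default to
  128/64; they are configuration, not fixed constants.
* **Augmentation** draws one spatial transform per sample — rotation
  ±15°, horizontal/vertical flips, zoom 0.8–1.2× — applied identically
  to image (bilinear) and mask (nearest-neighbour), plus a brightness
  factor 0.8–1.2× on the image only, clipped to [0, 1].
  Out-of-bounds regions after rotation or zoom-out are filled with 0
  for both image and mask, keeping masks binary. One seed reproduces
  one transform exactly.
* **Stratified splitting** apportions each class by largest remainder
  so the training set holds exactly `round(fraction × n)` items while
  every class stays within one sample of the global fraction. Pure
  per-class rounding cannot guarantee both (1113/1114 positives of
  2227 at 0.8 would give 1781, not 1782); largest-remainder
  apportionment satisfies the total and the per-class bound
  simultaneously.

## Training regimen

Adam (learning rate 10⁻⁴, weight decay 10⁻⁵ added to gradients as an L2
term), micro-batches of 8 with gradient accumulation over 2 steps
(effective batch 16), cosine annealing from the initial rate to a floor
of 0 over `max_epochs` (default 30), dynamic augmentation during
training, early stopping on validation loss with patience 10, and
restoration of the best-validation-loss weights. Validation loss means
the total multi-task loss at the training weights. Dropout (0.3) is
active in the decoder and the classifier head only.

Gradient accumulation averages the micro-batch mean gradients, so with
batch-norm statistics frozen two micro-batches of 4 produce the same
update as one batch of 8 to machine precision; `set_bn_frozen()`
exposes exactly that switch and the acceptance suite asserts the
equivalence at 10⁻⁵ relative tolerance.

## Evaluation

All classification metrics are derived from a TP/TN/FP/FN quadruple:
accuracy, precision, recall, F1, Dice = 2TP/(2TP+FP+FN) and IoU =
TP/(TP+FP+FN). On binary counts Dice equals F1 exactly and
Dice = 2·IoU/(1+IoU); the report object carries both and the tests
assert the identities in exact arithmetic. Zero denominators return 0
with a warning. ROC curves sweep the unique scores (ties grouped) with
trapezoidal AUC; the implementation is cross-checked against the
Mann–Whitney rank identity and against an independent library.

`evaluate_model()` tabulates confusion either over all mask pixels or
over image-level predictions, both at threshold 0.5. Image-level
Dice/IoU from image-level counts are reported alongside the pixel-level
versions, because published comparison tables of this kind print values
that equal the image-level confusion-count formulas exactly.

## Synthetic fixtures

The generator emulates what the pipeline needs from a stained cytology
scan, not its photorealism: a pale bright-field background with a
smooth illumination tilt, scattered small "normal cells" (dark bluish
nucleus inside a faint halo), and — with configurable probability —
one or more larger, irregular, hyperchromatic lesion blobs whose union
is exactly the binary mask. Lesion boundaries are deformed ellipses
(two random angular harmonics), so segmentation boundaries are
non-trivial and index-guided unpooling has something to reconstruct.
Additive Gaussian noise (σ = 0.02) exercises normalization and
augmentation robustness without corrupting labels. Everything is
reproducible from one seed.

What passing tests on these fixtures shows: the pipeline preserves
invariants, the network can learn and generalize within the generator's
distribution, and the training loop optimizes what it claims to. What
it does not show: performance on real Pap smear scans, robustness to
staining protocols, scanner noise, overlapping cell clusters, or
out-of-distribution lesions. The headline numbers of GPU-scale training
on thousands of real scans are out of reach at desk scale and are not
claimed; the published comparison-table values are reproduced from
their printed confusion counts as exact metric arithmetic instead.

## Scaled-down study sizes

Two capability runs back the "this actually learns" claim, sized for
single-CPU minutes:

* `fixture_overfit_study()`: 8 images, 64×64, lesion probability 0.75,
  tiny configuration (channels 8/16/32, 32-dim 2-block transformer,
  dropout 0), Adam 3·10⁻³, micro-batch 2, 100 epochs, no augmentation.
  The default indices-only decoder memorizes the 8 masks to a training
  Dice well above 0.95.
* `fixture_holdout_study()`: 32 images split 24/8 with stratification,
  same regimen, with the additive skip path (`skip_add = TRUE`)
  enabled. At this scale the indices-only decoder underfits (it
  plateaus below its own training-set ceiling), while the additive skip
  variant recovers held-out lesions almost perfectly; the run reports
  pixel Dice/IoU on the 8 held-out images.

The higher learning rate (3·10⁻³ versus the full-scale 10⁻⁴) reflects
the tiny parameter count and the short epoch budget; dropout is disabled
because regularization is counterproductive when the point is to
demonstrate capacity.

## Numerical choices

* Probability clamp 10⁻⁷ before logarithms; Dice ε = 10⁻⁶.
* Pooling ties break to the first window position in row-major order.
* The re-pool identity `pool(unpool(pool(x))) == pool(x)` holds on
  non-negative maps — the post-ReLU regime in which pooling actually
  operates; on signed inputs the zeros introduced by unpooling can
  out-rank an all-negative window.
* Classification and mask thresholds are 0.5.
* Checkpoint selection uses strict improvement (tolerance 0) of
  validation loss.
* Batch-norm momentum 0.1, ε 10⁻⁵; layer-norm ε 10⁻⁵.
* Internally feature maps are channel-first `(C, H, W, N)` so that
  im2col and per-channel normalization are plain reshapes; the public
  API keeps images in the `(H, W, C)` orientation R image packages use.

## Known limitations

* CPU-bound: full-scale 256×256 training is functional but slow in R;
  the package's evidence comes from the scaled-down studies above.
* No pretrained backbone weights (no download dependency), so transfer
  learning from natural images is out of scope.
* Binary masks only; no multi-class lesions, no whole-slide pyramids,
  no stain deconvolution.
* The distillation token is supervised by ground truth absent a
  teacher; distillation from a real teacher model is a hook, not a
  shipped feature.
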