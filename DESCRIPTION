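Package: cytomtl
Title: Joint Segmentation and Classification of Cervical Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-task deep learning for bright-field cervical cytology
    (Pap smear) images: a shared convolutional encoder with max-pooling
    indices feeds an index-guided unpooling decoder for pixel-wise lesion
    segmentation and, through a bottleneck residual feature bridge, a
    data-efficient transformer head with class and distillation tokens for
    image-level abnormality classification. Includes the full preprocessing
    pipeline (per-channel min-max normalization, paired bilinear/nearest
    resizing, overlapping patch extraction, stratified splitting, paired
    augmentation), the composite BCE+Dice multi-task loss with loss-weight
    grid search, a training loop with gradient accumulation, cosine
    annealing and early stopping, confusion-count metric algebra with
    ROC/AUC, ablation model variants, and a synthetic cytology-image
    generator so every component is testable without external data. The
    network forward and backward passes are implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
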