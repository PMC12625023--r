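# Deterministic preprocessing of image/mask pairs: per-channel min-max
# normalization, image-level label derivation, paired bilinear/nearest
# resizing, overlapping patch grids with margin clamping, paired
# augmentation, and stratified train/validation splitting.

#' Image/mask pair
#'
#' The universal sample unit: a normalized RGB-like image in \[0,1\], a
#' binary lesion mask of the same height/width, and the image-level label
#' derived from the mask (positive iff any foreground pixel).
#'
#' @param image numeric `H x W x C` array (values in \[0,1\]) or an integer
#'   array to be normalized first.
#' @param mask `H x W` array with values in `{0, 1}` (or 0/255, binarized).
#' @param sample_id identifier string.
#' @param normalize apply [normalize_image()] to `image`.
#' @return an object of class `image_mask_pair` with fields `image`,
#'   `mask`, `label`, `sample_id`.
#' @export
image_mask_pair <- function(image, mask, sample_id = "sample",
                            normalize = FALSE) {
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  if (normalize) image <- normalize_image(image)
  mask <- binarize_mask(mask)
  d <- dim(image)
  if (!all(dim(mask) == d[1:2]))
    stop("image and mask must share height and width")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must lie in [0,1]; use normalize = TRUE for raw input")
  structure(list(image = image, mask = mask, label = derive_label(mask),
                 sample_id = as.character(sample_id)),
            class = "image_mask_pair")
}

binarize_mask <- function(mask) {
  mask <- as.matrix(mask)
  u <- unique(as.vector(mask))
  if (all(u %in% c(0, 1))) storage.mode(mask) <- "integer"
  else if (all(u %in% c(0, 255))) { mask <- (mask > 0) * 1L; }
  else if (all(u >= 0 & u <= 1)) mask <- (mask > 0) * 1L   # e.g. 255 scaled by PNG read
  else stop("mask is not binary (values other than 0/1 or 0/255 found)")
  mask * 1L
}

#' Per-channel min-max normalization
#'
#' Rescales each channel of an image independently to \[0,1\]:
#' `(x - min_c) / (max_c - min_c)`. A constant channel maps to all zeros
#' (by convention; the degenerate denominator never divides).
#'
#' @param raw_image numeric `H x W x C` (or `H x W`) array.
#' @return array of the same shape with values in \[0,1\].
#' @export
normalize_image <- function(raw_image) {
  if (length(raw_image) == 0) stop("empty image")
  d <- dim(raw_image)
  if (is.null(d)) stop("raw_image must be a matrix or array")
  if (length(d) == 2) dim(raw_image) <- d <- c(d, 1L)
  out <- raw_image
  for (c in seq_len(d[3])) {
    ch <- raw_image[, , c]
    lo <- min(ch); hi <- max(ch)
    out[, , c] <- if (hi > lo) (ch - lo) / (hi - lo) else 0
  }
  out
}

#' Derive the image-level label from a mask
#'
#' Positive (1) iff the binary mask contains at least one foreground pixel.
#' @param mask binary matrix.
#' @return 0 or 1.
#' @export
derive_label <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  as.integer(any(mask == 1))
}

# (H,W,C) <-> EBImage's width-major (x = W, y = H, c) layout.
to_eb <- function(a) {
  if (length(dim(a)) == 2) aperm(a, c(2, 1)) else aperm(a, c(2, 1, 3))
}
from_eb <- function(a) {
  if (length(dim(a)) == 2) aperm(a, c(2, 1)) else aperm(a, c(2, 1, 3))
}

resize_array <- function(a, target_hw, filter) {
  eb <- EBImage::resize(EBImage::Image(to_eb(a)),
                        w = target_hw[2], h = target_hw[1], filter = filter)
  from_eb(EBImage::imageData(eb))
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour interpolation (so it stays binary), and the label is
#' re-derived from the resized mask (a one-pixel lesion can vanish under
#' nearest-neighbour downscaling).
#'
#' @param pair an [image_mask_pair()].
#' @param target integer `(H, W)`.
#' @export
resize_pair <- function(pair, target) {
  stopifnot(inherits(pair, "image_mask_pair"), all(target >= 1))
  d <- dim(pair$image)
  if (all(d[1:2] == target)) return(pair)
  img <- resize_array(pair$image, target, "bilinear")
  img[] <- pmin(pmax(img, 0), 1)
  msk <- resize_array(pair$mask * 1.0, target, "none")
  image_mask_pair(img, msk, pair$sample_id)
}

#' Overlapping patch grid
#'
#' Top-left origins (0-based, `(row, col)`) of `patch_size`-square windows
#' laid out at `stride` steps; the final origin on each axis is clamped to
#' `dim - patch_size` so the grid covers every pixel, including margins.
#'
#' @param image_dims integer `(H, W)`.
#' @param patch_size window side in pixels; at most `min(H, W)`.
#' @param stride step in pixels, `0 < stride <= patch_size` for guaranteed
#'   coverage.
#' @return list of class `patch_grid` with `patch_size`, `stride`,
#'   `origins` (two-column matrix of 0-based row/col).
#' @export
build_patch_grid <- function(image_dims, patch_size, stride) {
  H <- image_dims[1]; W <- image_dims[2]
  if (patch_size > min(H, W)) stop("patch_size exceeds image dimension")
  if (stride <= 0 || stride > patch_size)
    stop("stride must satisfy 0 < stride <= patch_size")
  axis_origins <- function(n) {
    o <- seq(0L, max(0L, n - patch_size), by = stride)
    unique(c(o, n - patch_size))            # clamp final origin to cover margin
  }
  og <- expand.grid(row = axis_origins(H), col = axis_origins(W),
                    KEEP.OUT.ATTRS = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 origins = as.matrix(og)),
            class = "patch_grid")
}

#' Extract the patches of a grid from a pair
#'
#' @param pair an [image_mask_pair()].
#' @param grid a [build_patch_grid()] for the pair's dimensions.
#' @return list of `image_mask_pair` patches (ids suffixed with the origin).
#' @export
extract_patches <- function(pair, grid) {
  P <- grid$patch_size
  lapply(seq_len(nrow(grid$origins)), function(i) {
    r <- grid$origins[i, 1]; cc <- grid$origins[i, 2]
    image_mask_pair(pair$image[(r + 1):(r + P), (cc + 1):(cc + P), , drop = FALSE],
                    pair$mask[(r + 1):(r + P), (cc + 1):(cc + P)],
                    sprintf("%s_r%d_c%d", pair$sample_id, r, cc))
  })
}

#' Paired train-time augmentation
#'
#' Random rotation (+-15 degrees), horizontal/vertical flips (each with
#' probability 1/2), zoom (0.8-1.2x) and brightness scaling (0.8-1.2x,
#' image only, clipped to \[0,1\]). The identical spatial transform is
#' applied to image (bilinear) and mask (nearest-neighbour); rotation and
#' zoom-out fill out-of-bounds regions with 0. The same seed reproduces the
#' same augmentation.
#'
#' @param pair an [image_mask_pair()].
#' @param seed integer driving all random draws.
#' @param params optional fixed transform instead of random draws: a list
#'   with any of `angle`, `hflip`, `vflip`, `zoom`, `brightness`
#'   (unlisted components default to the identity).
#' @return augmented `image_mask_pair` (label re-derived).
#' @export
augment_pair <- function(pair, seed = 1L, params = NULL) {
  with_seed(seed, {
    if (is.null(params)) {
      angle <- stats::runif(1, -15, 15)
      hflip <- stats::runif(1) < 0.5
      vflip <- stats::runif(1) < 0.5
      zoom <- stats::runif(1, 0.8, 1.2)
      bright <- stats::runif(1, 0.8, 1.2)
    } else {
      angle <- params$angle %||% 0
      hflip <- isTRUE(params$hflip)
      vflip <- isTRUE(params$vflip)
      zoom <- params$zoom %||% 1
      bright <- params$brightness %||% 1
    }
    img <- pair$image
    msk <- pair$mask * 1.0
    d <- dim(img)
    if (hflip) { img <- img[, d[2]:1, , drop = FALSE]; msk <- msk[, d[2]:1] }
    if (vflip) { img <- img[d[1]:1, , , drop = FALSE]; msk <- msk[d[1]:1, ] }
    if (abs(angle) > 1e-8) {
      img <- rotate_array(img, angle, "bilinear")
      msk <- rotate_array(msk, angle, "none")
    }
    if (abs(zoom - 1) > 1e-8) {
      img <- zoom_array(img, zoom, "bilinear")
      msk <- zoom_array(msk, zoom, "none")
    }
    img <- pmin(pmax(img * bright, 0), 1)
    image_mask_pair(img, msk, pair$sample_id)
  })
}

rotate_array <- function(a, angle, filter) {
  d <- dim(a)
  eb <- EBImage::rotate(EBImage::Image(to_eb(a)), angle, filter = filter,
                        output.dim = c(d[2], d[1]), bg.col = 0)
  out <- from_eb(EBImage::imageData(eb))
  if (filter == "bilinear") out[] <- pmin(pmax(out, 0), 1)
  out
}

# Zoom about the image centre at constant output size: scale, then
# centre-crop (zoom in) or zero-pad (zoom out).
zoom_array <- function(a, factor, filter) {
  d <- dim(a)
  is2d <- length(d) == 2
  H <- d[1]; W <- d[2]
  Hs <- max(1L, round(H * factor)); Ws <- max(1L, round(W * factor))
  s <- resize_array(a, c(Hs, Ws), filter)
  if (is2d) dim(s) <- c(Hs, Ws, 1L) else dim(s) <- c(Hs, Ws, d[3])
  out <- array(0, c(H, W, dim(s)[3]))
  hr <- min(H, Hs); wr <- min(W, Ws)
  ofo <- c((H - hr) %/% 2L, (W - wr) %/% 2L)   # offset in output
  ofs <- c((Hs - hr) %/% 2L, (Ws - wr) %/% 2L) # offset in source
  out[(ofo[1] + 1):(ofo[1] + hr), (ofo[2] + 1):(ofo[2] + wr), ] <-
    s[(ofs[1] + 1):(ofs[1] + hr), (ofs[2] + 1):(ofs[2] + wr), , drop = FALSE]
  if (is2d) dim(out) <- c(H, W)
  out
}

#' Stratified train/validation split
#'
#' Partitions indices so that the training set holds `round(fraction * n)`
#' items and every class is represented at the same fraction (largest-
#' remainder apportionment; per-class counts deviate from the exact
#' fraction by at most one sample, remainder going to validation).
#' Reproducible under `seed`; a class with fewer than 2 members goes
#' entirely to training with a warning.
#'
#' @param labels vector of binary (or categorical) labels.
#' @param train_fraction real in (0,1); default 0.8.
#' @param seed integer RNG seed for the within-class shuffles.
#' @return list with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  n <- length(labels)
  if (n == 0) stop("labels must be non-empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)")
  target <- floor(train_fraction * n + 0.5)
  cls <- split(seq_len(n), as.character(labels))
  small <- vapply(cls, length, integer(1)) < 2L
  if (any(small))
    warning("class(es) with fewer than 2 members assigned entirely to training: ",
            paste(names(cls)[small], collapse = ", "))
  ideal <- vapply(cls, length, integer(1)) * train_fraction
  take <- floor(ideal)
  take[small] <- vapply(cls, length, integer(1))[small]
  remaining <- target - sum(take)
  if (remaining > 0) {
    frac <- ideal - floor(ideal)
    frac[small] <- -Inf
    ord <- order(-frac, -vapply(cls, length, integer(1)), names(cls))
    for (i in ord) {
      if (remaining <= 0) break
      if (take[i] < length(cls[[i]])) { take[i] <- take[i] + 1L; remaining <- remaining - 1L }
    }
  }
  train <- integer(0)
  with_seed(seed, {
    for (i in seq_along(cls)) {
      idx <- cls[[i]]
      perm <- if (length(idx) > 1) sample(idx) else idx
      train <- c(train, perm[seq_len(min(take[i], length(idx)))])
    }
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_len(n), train))
}

# -- dataset manifest / PNG loading ------------------------------------------

#' Read a dataset manifest and load the pairs
#'
#' The manifest is a CSV with columns `sample_id`, `image_path`,
#' `mask_path` (paths relative to the manifest's directory unless
#' absolute). Masks are binarized at > 0 on load; images are normalized
#' per channel.
#'
#' @param manifest_path path to the CSV.
#' @param normalize per-channel min-max normalize images on load (set to
#'   FALSE for data already in \[0,1\] that must round-trip unchanged).
#' @return list of [image_mask_pair()] objects.
#' @export
read_dataset <- function(manifest_path, normalize = TRUE) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "image_path", "mask_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(resolve(man$image_path[i]))
    msk <- png::readPNG(resolve(man$mask_path[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    if (normalize) img <- normalize_image(img)
    image_mask_pair(img, (msk > 0) * 1L, man$sample_id[i])
  })
}

#' Write a split assignment as CSV
#' @param split result of [stratified_split()].
#' @param sample_ids ids in index order.
#' @param path output CSV path (columns `sample_id`, `partition`).
#' @export
write_split_csv <- function(split, sample_ids, path) {
  df <- data.frame(
    sample_id = sample_ids[c(split$train, split$validation)],
    partition = rep(c("train", "validation"),
                    c(length(split$train), length(split$validation))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
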