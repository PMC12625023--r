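# Synthetic bright-field cytology-like images with paired binary lesion
# masks. Backgrounds are light with a faint smooth tint, "normal" cells
# are small round blobs (dark nucleus, faint cytoplasm halo), and
# "abnormal" lesions are larger irregular blobs (deformed ellipse
# boundary, hyperchromatic colouring, internal texture). The mask is
# exactly the union of the lesion regions, so the image-level label is
# positive iff a lesion was drawn.

#' Synthetic dataset configuration
#'
#' @param n_images number of image/mask pairs.
#' @param image_size integer `(H, W)`; 64x64 suits unit tests, 256x256
#'   integration tests.
#' @param lesion_probability probability that an image carries lesions
#'   (and hence a positive label).
#' @param lesion_count_range integer `(min, max)` lesions per positive
#'   image.
#' @param lesion_radius_range `(min, max)` mean lesion radius in pixels.
#' @param background_cell_count normal-cell blobs per image.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (clipped to \[0,1\]).
#' @param seed integer; generation is fully reproducible from it.
#' @export
synth_config <- function(n_images = 16L,
                         image_size = c(64L, 64L),
                         lesion_probability = 0.5,
                         lesion_count_range = c(1L, 3L),
                         lesion_radius_range = c(5, 12),
                         background_cell_count = 12L,
                         noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(n_images >= 1, all(image_size >= 8),
            lesion_probability >= 0, lesion_probability <= 1,
            lesion_count_range[1] >= 1,
            lesion_count_range[2] >= lesion_count_range[1],
            lesion_radius_range[1] >= 2, noise_sd >= 0)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 lesion_probability = lesion_probability,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 background_cell_count = as.integer(background_cell_count),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Irregular blob membership on the pixel grid: boundary radius is a mean
# radius modulated by two random angular harmonics.
blob_mask <- function(H, W, cy, cx, r, wobble = c(0.25, 0.15)) {
  ys <- matrix(seq_len(H), H, W) - cy
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  th <- atan2(ys, xs)
  a1 <- stats::runif(1, -1, 1) * wobble[1]
  a2 <- stats::runif(1, -1, 1) * wobble[2]
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  rb <- r * (1 + a1 * cos(2 * th + p1) + a2 * cos(3 * th + p2))
  sqrt(ys^2 + xs^2) <= pmax(rb, 1)
}

generate_one <- function(cfg, id) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  # pale pink-ish bright-field background with a smooth illumination tint
  base <- c(0.92, 0.87, 0.90)
  gy <- matrix(seq_len(H) / H, H, W)
  gx <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  tilt <- 0.04 * (gy * stats::runif(1, -1, 1) + gx * stats::runif(1, -1, 1))
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- base[c] + tilt
  # normal cells: faint halo + small dark bluish nucleus
  for (k in seq_len(cfg$background_cell_count)) {
    cy <- stats::runif(1, 3, H - 2); cx <- stats::runif(1, 3, W - 2)
    rn <- stats::runif(1, 1.5, 3.5)
    halo <- blob_mask(H, W, cy, cx, rn * stats::runif(1, 1.8, 2.6), c(0.1, 0.05))
    nuc <- blob_mask(H, W, cy, cx, rn, c(0.15, 0.1))
    tint <- c(0.85, 0.82, 0.92)
    dark <- c(0.45, 0.40, 0.65)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[halo] <- ch[halo] * tint[c]
      ch[nuc] <- dark[c] * stats::runif(1, 0.9, 1.1)
      img[, , c] <- ch
    }
  }
  # abnormal lesions: larger, irregular, hyperchromatic magenta-dark
  mask <- matrix(0L, H, W)
  if (stats::runif(1) < cfg$lesion_probability) {
    n_les <- sample(cfg$lesion_count_range[1]:cfg$lesion_count_range[2], 1)
    for (k in seq_len(n_les)) {
      r <- stats::runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
      r <- min(r, (min(H, W) - 2) / 2)
      cy <- stats::runif(1, r + 1, H - r); cx <- stats::runif(1, r + 1, W - r)
      les <- blob_mask(H, W, cy, cx, r)
      col <- c(0.40, 0.12, 0.38) * stats::runif(1, 0.85, 1.1)
      tex <- 0.06 * matrix(stats::rnorm(H * W), H, W)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[les] <- col[c] + tex[les]
        img[, , c] <- ch
      }
      mask[les] <- 1L
    }
  }
  if (cfg$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = cfg$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  image_mask_pair(img, mask, id)
}

#' Generate a synthetic cytology dataset
#'
#' @param config a [synth_config()].
#' @return list of [image_mask_pair()] objects; identical seeds give
#'   bit-identical datasets.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (prod(config$image_size) == 0) stop("zero-area image")
  with_seed(config$seed,
            lapply(seq_len(config$n_images), function(i)
              generate_one(config, sprintf("synth_%03d", i))))
}

#' Write a fixture set to disk
#'
#' Writes one image PNG and one mask PNG per pair plus a CSV manifest
#' compatible with [read_dataset()].
#'
#' @param pairs non-empty list of [image_mask_pair()] objects.
#' @param directory output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_fixture_set <- function(pairs, directory) {
  if (length(pairs) == 0) stop("empty pair list")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", directory)
  rows <- lapply(pairs, function(p) {
    ip <- paste0(p$sample_id, "_image.png")
    mp <- paste0(p$sample_id, "_mask.png")
    png::writePNG(p$image, file.path(directory, ip))
    png::writePNG(p$mask * 1.0, file.path(directory, mp))
    data.frame(sample_id = p$sample_id, image_path = ip, mask_path = mp)
  })
  manifest <- file.path(directory, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
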