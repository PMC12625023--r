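#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Half-up rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Stack image/mask pairs into batch arrays
#'
#' Converts a list of [image_mask_pair()] objects sharing one geometry into
#' the batch arrays consumed by the network: images as `H x W x C x N`,
#' masks as `H x W x N`, labels as a length-`N` vector.
#'
#' @param pairs list of `image_mask_pair` objects with identical dimensions.
#' @return list with elements `x`, `masks`, `labels`, `sample_ids`.
#' @export
stack_pairs <- function(pairs) {
  stopifnot(length(pairs) > 0)
  d <- dim(pairs[[1]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(pairs)))
  m <- array(0L, c(d[1], d[2], length(pairs)))
  for (i in seq_along(pairs)) {
    if (!identical(dim(pairs[[i]]$image), d))
      stop("all pairs must share image dimensions")
    x[, , , i] <- pairs[[i]]$image
    m[, , i] <- pairs[[i]]$mask
  }
  list(x = x, masks = m,
       labels = vapply(pairs, function(p) p$label, numeric(1)),
       sample_ids = vapply(pairs, function(p) p$sample_id, character(1)))
}

clamp01 <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)
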