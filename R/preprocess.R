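# The radiograph preprocessing stack: intensity scaling to [0, 1],
# histogram equalization, z-scoring, gamma contrast, bilinear/nearest
# resizing, and seeded horizontal-flip augmentation. All intensity ops
# preserve the grid shape and spacing; resize rescales spacing by the size
# ratio so physical areas are conserved.

#' Preprocessing configuration
#'
#' @param scale_min,scale_max target intensity range for [scale_intensity()].
#' @param gamma contrast exponent for [adjust_contrast_gamma()]; the default
#'   1.6 darkens dark regions and brightens bright ones.
#' @param resize_shape (rows, cols) training shape for [resize_pair()].
#' @param flip_prob horizontal-flip probability used in training augmentation.
#' @param histogram_bins number of bins for [histogram_normalize()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(scale_min = 0, scale_max = 1, gamma = 1.6,
                              resize_shape = c(512, 1024), flip_prob = 0.5,
                              histogram_bins = 256) {
  if (scale_min >= scale_max) stop("scale_min must be < scale_max")
  if (gamma <= 0) stop("gamma must be > 0")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0, 1]")
  if (histogram_bins < 2) stop("histogram_bins must be >= 2")
  structure(list(scale_min = scale_min, scale_max = scale_max, gamma = gamma,
                 resize_shape = as.integer(resize_shape), flip_prob = flip_prob,
                 histogram_bins = as.integer(histogram_bins)),
            class = "preprocess_config")
}

#' Scale intensities to a target range
#'
#' Affine map of the observed range onto `[min, max]`. A constant image maps
#' to `min` everywhere (degenerate-range convention).
#'
#' @param img a [image2d()].
#' @param min,max target range.
#' @return A [image2d()] with the same shape and spacing.
#' @export
scale_intensity <- function(img, min = 0, max = 1) {
  stopifnot(inherits(img, "limb_image"))
  v <- img$values
  rng <- range(v)
  out <- if (rng[1] == rng[2]) matrix(min, nrow(v), ncol(v))
         else min + (v - rng[1]) / (rng[2] - rng[1]) * (max - min)
  image2d(out, img$spacing)
}

#' Histogram equalization
#'
#' Redistributes intensities so the output histogram is approximately
#' uniform on \[0, 1\]: pixels are binned over the observed range and mapped
#' to the empirical CDF of their bin. The mapping is monotone non-decreasing,
#' so pixel rank order is preserved up to ties; applying it twice changes the
#' result only within bin quantization.
#'
#' @param img a [image2d()].
#' @param bins number of histogram bins (>= 2).
#' @return A [image2d()] with values in \[0, 1\].
#' @export
histogram_normalize <- function(img, bins = 256) {
  stopifnot(inherits(img, "limb_image"))
  if (bins < 2) stop("bins must be >= 2")
  v <- img$values
  rng <- range(v)
  if (rng[1] == rng[2]) return(image2d(matrix(1, nrow(v), ncol(v)), img$spacing))
  idx <- pmin(bins, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * bins))
  cdf <- cumsum(tabulate(idx, nbins = bins)) / length(v)
  image2d(matrix(cdf[idx], nrow(v), ncol(v)), img$spacing)
}

#' Z-score intensity normalization
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor `n`, not `n - 1`; at image scale the difference is negligible but
#' the convention is fixed for reproducibility). A constant image maps to all
#' zeros.
#'
#' @param img a [image2d()].
#' @return A [image2d()] with mean 0 and population sd 1.
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "limb_image"))
  v <- img$values
  mu <- mean(v)
  sdp <- sqrt(mean((v - mu)^2))
  out <- if (sdp == 0) matrix(0, nrow(v), ncol(v)) else (v - mu) / sdp
  image2d(out, img$spacing)
}

#' Gamma contrast adjustment
#'
#' Min-max normalizes internally, raises to the power `gamma`, and maps back
#' to the original range, so the endpoints are fixed and the transform is
#' well defined even on z-scored (negative) intensities. `gamma > 1`
#' increases contrast; `gamma = 1` is the identity. A constant image is
#' returned unchanged.
#'
#' @param img a [image2d()].
#' @param gamma positive exponent.
#' @return A [image2d()].
#' @export
adjust_contrast_gamma <- function(img, gamma = 1.6) {
  stopifnot(inherits(img, "limb_image"))
  if (gamma <= 0) stop("gamma must be > 0")
  v <- img$values
  rng <- range(v)
  if (rng[1] == rng[2]) return(img)
  u <- (v - rng[1]) / (rng[2] - rng[1])
  image2d(rng[1] + u^gamma * (rng[2] - rng[1]), img$spacing)
}

#' Resize an image/mask pair
#'
#' The image is resampled with bilinear interpolation, the mask with
#' nearest-neighbor (so the output label set is a subset of the input's).
#' Spacing is rescaled by the size ratio, conserving the physical field of
#' view and hence region areas up to boundary pixels.
#'
#' @param img a [image2d()].
#' @param mask a [labelmap()] on the same grid (or NULL).
#' @param shape target (rows, cols).
#' @return A list with `image` and `mask`.
#' @export
resize_pair <- function(img, mask = NULL, shape) {
  stopifnot(inherits(img, "limb_image"))
  if (!is.null(mask) && !same_grid(img, mask))
    stop("image and mask shapes differ")
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("target shape must be positive")
  H <- nrow(img$values); W <- ncol(img$values)
  new_spacing <- c(img$spacing[1] * H / shape[1], img$spacing[2] * W / shape[2])
  if (identical(shape, c(H, W)))
    return(list(image = img, mask = mask))
  # source coordinates of output pixel centers (half-pixel convention),
  # clamped to the valid center range [1, n]
  rr <- pmin(pmax((seq_len(shape[1]) - 0.5) * H / shape[1] + 0.5, 1), H)
  cc <- pmin(pmax((seq_len(shape[2]) - 0.5) * W / shape[2] + 0.5, 1), W)
  rlo <- floor(rr); rhi <- pmin(rlo + 1, H); rfrac <- rr - rlo
  clo <- floor(cc); chi <- pmin(clo + 1, W); cfrac <- cc - clo
  v <- img$values
  out <- (1 - rfrac) %o% (1 - cfrac) * v[rlo, clo, drop = FALSE] +
         (1 - rfrac) %o% cfrac       * v[rlo, chi, drop = FALSE] +
         rfrac %o% (1 - cfrac)       * v[rhi, clo, drop = FALSE] +
         rfrac %o% cfrac             * v[rhi, chi, drop = FALSE]
  new_img <- image2d(out, new_spacing)
  new_mask <- NULL
  if (!is.null(mask)) {
    rn <- pmin(pmax(round(rr), 1), H); cn <- pmin(pmax(round(cc), 1), W)
    new_mask <- labelmap(mask$codes[rn, cn, drop = FALSE], new_spacing, mask$schema)
  }
  list(image = new_img, mask = new_mask)
}

#' Seeded horizontal flip augmentation
#'
#' With probability `p`, mirrors the image and mask jointly about the
#' vertical axis (column reversal). Side-specific class labels (lateral /
#' medial) are not swapped: the flip is purely geometric.
#'
#' @param img a [image2d()].
#' @param mask a [labelmap()] or NULL.
#' @param p flip probability in \[0, 1\].
#' @param rng_seed integer seed making the draw reproducible.
#' @return List with `image`, `mask`, and `flipped` (logical).
#' @export
random_flip_pair <- function(img, mask = NULL, p = 0.5, rng_seed = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  flipped <- with_seed(rng_seed, runif(1) < p)
  if (flipped) {
    img <- image2d(img$values[, rev(seq_len(ncol(img$values))), drop = FALSE], img$spacing)
    if (!is.null(mask))
      mask <- labelmap(mask$codes[, rev(seq_len(ncol(mask$codes))), drop = FALSE],
                       mask$spacing, mask$schema)
  }
  list(image = img, mask = mask, flipped = flipped)
}

#' Full deterministic preprocessing pipeline
#'
#' Applies, in order: [scale_intensity()], [histogram_normalize()],
#' [normalize_intensity()], [adjust_contrast_gamma()]. Augmentation (random
#' flip) is a training-time concern and is deliberately excluded, so two runs
#' on the same image are identical.
#'
#' @param img a [image2d()].
#' @param cfg a [preprocess_config()].
#' @return A [image2d()].
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  img <- scale_intensity(img, cfg$scale_min, cfg$scale_max)
  img <- histogram_normalize(img, cfg$histogram_bins)
  img <- normalize_intensity(img)
  adjust_contrast_gamma(img, cfg$gamma)
}
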