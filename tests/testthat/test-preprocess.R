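rand_img <- function(nr = 32, nc = 16, seed = 1, spacing = c(1, 1)) {
  set.seed(seed)
  image2d(matrix(runif(nr * nc), nr, nc), spacing)
}

test_that("scale_intensity maps the observed range affinely with the constant convention", {
  img <- image2d(matrix(c(1, 2, 3, 1, 2, 3), 2, 3))
  out <- scale_intensity(img, 0, 1)
  expect_equal(sort(unique(as.vector(out$values))), c(0, 0.5, 1))
  const <- scale_intensity(image2d(matrix(7, 4, 4)), 0, 1)
  expect_true(all(const$values == 0))
  already <- image2d(matrix(seq(0, 1, length.out = 16), 4, 4))
  expect_equal(scale_intensity(already)$values, already$values)
})

test_that("histogram equalization preserves rank order and approaches uniformity", {
  two <- image2d(matrix(rep(c(0.2, 0.9), each = 8), 4, 4))
  out <- histogram_normalize(two, bins = 16)
  expect_equal(length(unique(as.vector(out$values))), 2)
  expect_equal(out$values[two$values == 0.2][1] < out$values[two$values == 0.9][1], TRUE)
  expect_true(all(out$values >= 0 & out$values <= 1))
  # continuous input -> output CDF close to uniform (KS distance)
  img <- rand_img(128, 64, seed = 2)
  eq <- histogram_normalize(img, 256)
  v <- sort(as.vector(eq$values))
  ks <- max(abs(v - seq_along(v) / length(v)))
  expect_lt(ks, 0.02)
  # idempotent within bin quantization
  eq2 <- histogram_normalize(eq, 256)
  expect_lt(max(abs(eq2$values - eq$values)), 2 / 256)
  # rank preservation on random pixel pairs
  set.seed(3)
  i <- sample(length(img$values), 500, replace = TRUE)
  j <- sample(length(img$values), 500, replace = TRUE)
  expect_true(all(sign(eq$values[i] - eq$values[j]) ==
                  sign(img$values[i] - img$values[j]) |
                  eq$values[i] == eq$values[j]))
  expect_error(histogram_normalize(img, 1), "bins")
})

test_that("z-score normalization uses the population sd and zeroes constants", {
  half <- image2d(matrix(rep(c(0, 1), each = 8), 4, 4))
  out <- normalize_intensity(half)
  expect_equal(sort(unique(as.vector(out$values))), c(-1, 1))
  expect_true(all(normalize_intensity(image2d(matrix(3, 4, 4)))$values == 0))
  img <- rand_img(64, 32, seed = 4)
  out <- normalize_intensity(img)
  expect_lt(abs(mean(out$values)), 1e-6)
  expect_equal(sqrt(mean(out$values^2)), 1, tolerance = 1e-10)
})

test_that("gamma adjustment fixes endpoints and matches direct exponentiation", {
  img <- image2d(matrix(c(0, 0.5, 1, 0.25), 2, 2))
  out <- adjust_contrast_gamma(img, 1.6)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[1, 2], 1)
  expect_equal(out$values[2, 1], 0.5^1.6)
  expect_equal(adjust_contrast_gamma(img, 1)$values, img$values)
  const <- image2d(matrix(2, 3, 3))
  expect_equal(adjust_contrast_gamma(const, 1.6)$values, const$values)
})

test_that("resize interpolates the image, nearest-neighbors the mask, and rescales spacing", {
  img <- rand_img(32, 16, seed = 5, spacing = c(1, 1))
  codes <- matrix(0L, 32, 16); codes[9:18, 4:13] <- 4L  # 10 x 10 mm region
  mask <- labelmap(codes, c(1, 1))
  same <- resize_pair(img, mask, c(32, 16))
  expect_identical(same$image$values, img$values)
  expect_identical(same$mask$codes, mask$codes)
  down <- resize_pair(img, mask, c(16, 8))
  expect_equal(down$image$spacing, c(2, 2))
  expect_true(all(unique(as.vector(down$mask$codes)) %in% unique(as.vector(codes))))
  # physical area preserved within one boundary pixel per edge
  a0 <- region_areas(mask)$total_muscle_cm2
  a1 <- region_areas(down$mask)$total_muscle_cm2
  edge_px_cm2 <- 10 * 2 * 2 * 2 / 100   # one 2mm boundary ring around 10mm square
  expect_lt(abs(a1 - a0), edge_px_cm2)
  expect_error(resize_pair(img, labelmap(matrix(0L, 4, 4), c(1, 1)), c(16, 8)),
               "shapes differ")
})

test_that("horizontal flip is a seeded joint involution", {
  img <- rand_img(16, 8, seed = 6)
  codes <- matrix(0L, 16, 8); codes[2, 1] <- 3L
  mask <- labelmap(codes, c(1, 1))
  none <- random_flip_pair(img, mask, p = 0, rng_seed = 1)
  expect_false(none$flipped)
  expect_identical(none$image$values, img$values)
  once <- random_flip_pair(img, mask, p = 1, rng_seed = 1)
  expect_true(once$flipped)
  expect_equal(once$mask$codes[2, 8], 3L)
  twice <- random_flip_pair(once$image, once$mask, p = 1, rng_seed = 2)
  expect_identical(twice$image$values, img$values)
  expect_identical(twice$mask$codes, mask$codes)
  # empirical flip frequency at p = 0.5
  flips <- vapply(1:10000, function(s)
    random_flip_pair(img, NULL, p = 0.5, rng_seed = s)$flipped, TRUE)
  expect_gt(mean(flips), 0.48)
  expect_lt(mean(flips), 0.52)
})

test_that("the full pipeline is deterministic and equals manual composition", {
  img <- rand_img(64, 32, seed = 7)
  cfg <- preprocess_config()
  out1 <- preprocess_pipeline(img, cfg)
  out2 <- preprocess_pipeline(img, cfg)
  expect_identical(out1$values, out2$values)
  manual <- adjust_contrast_gamma(
    normalize_intensity(histogram_normalize(scale_intensity(img, 0, 1), 256)), 1.6)
  expect_equal(out1$values, manual$values)
  # constant image ends all-zero
  const <- image2d(matrix(5, 8, 8))
  expect_true(all(preprocess_pipeline(const, cfg)$values == 0))
  # shape and spacing preserved by every intensity op
  expect_equal(out1$spacing, img$spacing)
  expect_equal(dim(out1$values), dim(img$values))
})
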