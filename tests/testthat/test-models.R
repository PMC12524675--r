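tiny_cfg <- function(arch, ...) {
  train_config(arch, "desk", input_shape = c(16, 8), depth = 2L,
               channels = c(3L, 5L), batch_size = 1, flip_prob = 0, ...)
}

rand_input <- function(cfg, seed = 1) {
  set.seed(seed)
  image2d(matrix(rnorm(prod(cfg$input_shape)), cfg$input_shape[1]), c(1, 1))
}

test_that("every architecture honors the shape contract and seeded init", {
  for (arch in c("unet", "vnet2d", "unetpp")) {
    cfg <- tiny_cfg(arch, seed = 9)
    m1 <- build_model(cfg)
    m2 <- build_model(cfg)
    expect_equal(m1$params, m2$params, info = arch)
    img <- rand_input(cfg)
    pred <- segment_image(m1, img)
    expect_equal(dim(pred$codes), cfg$input_shape, info = arch)
    expect_true(all(pred$codes %in% cfg$schema$code), info = arch)
    expect_equal(pred$spacing, img$spacing, info = arch)
    probs <- predict_probs(m1, img)
    expect_equal(dim(probs), c(cfg$input_shape, cfg$n_classes), info = arch)
    expect_equal(rowSums(matrix(probs, ncol = cfg$n_classes))[1:5], rep(1, 5),
                 info = arch)
  }
  expect_error(train_config("resnet"), "arg")
})

test_that("U-Net++ deep supervision exposes one head per nested decoder column", {
  cfg <- train_config("unetpp", "desk", input_shape = c(16, 8), depth = 3L,
                      channels = c(2L, 3L, 4L), deep_supervision = TRUE)
  m <- build_model(cfg)
  pn <- limbseg:::param_nodes(m$params)
  geoms <- limbseg:::level_geoms(16, 8, 3)
  x <- limbseg:::ag_node(matrix(rnorm(16 * 8), ncol = 1))
  heads <- limbseg:::model_forward("unetpp", cfg, pn, x, geoms)
  expect_gte(length(heads), 2)
  cfg2 <- train_config("unetpp", "desk", input_shape = c(16, 8), depth = 3L,
                       channels = c(2L, 3L, 4L), deep_supervision = FALSE)
  heads2 <- limbseg:::model_forward("unetpp", cfg2, limbseg:::param_nodes(build_model(cfg2)$params), x, geoms)
  expect_length(heads2, 1)
})

test_that("dice_loss matches a direct-summation oracle and its boundary cases", {
  sch <- plain_schema(1)
  lab <- labelmap(matrix(rep(c(0L, 1L), each = 8), 4, 4), c(1, 1), sch)
  onehot <- limbseg:::onehot_codes(lab$codes, sch)
  expect_equal(dice_loss(onehot, lab), 0)            # perfect one-hot
  expect_equal(dice_loss(1 - onehot, lab), 1, tolerance = 1e-5)  # complement
  # uniform 0.5/0.5 prediction, balanced classes: brute-force soft Dice
  P <- matrix(0.5, 16, 2)
  oracle <- 1 - mean(vapply(1:2, function(c) {
    i <- sum(P[, c] * onehot[, c]); a <- sum(P[, c]) + sum(onehot[, c])
    2 * i / a
  }, 0))
  expect_equal(dice_loss(P, lab), oracle, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0.5, 4, 2), lab), "shapes differ")
})

test_that("autograd gradients match finite differences on all architectures", {
  for (arch in c("unet", "vnet2d", "unetpp")) {
    cfg <- tiny_cfg(arch, seed = 3)
    model <- build_model(cfg)
    geoms <- limbseg:::level_geoms(16, 8, cfg$depth)
    set.seed(4)
    X <- matrix(rnorm(16 * 8), ncol = 1)
    G <- limbseg:::onehot_codes(matrix(sample(0:7, 16 * 8, TRUE), 16, 8), cfg$schema)
    loss_of <- function(params) {
      pn <- limbseg:::param_nodes(params)
      heads <- limbseg:::model_forward(arch, cfg, pn, limbseg:::ag_node(X), geoms)
      ls <- lapply(heads, limbseg:::ag_dice_loss, G = G, class_idx = 1:8)
      Reduce(limbseg:::ag_add, ls)$val / length(ls)
    }
    pn <- limbseg:::param_nodes(model$params)
    heads <- limbseg:::model_forward(arch, cfg, pn, limbseg:::ag_node(X), geoms)
    ls <- lapply(heads, limbseg:::ag_dice_loss, G = G, class_idx = 1:8)
    limbseg:::ag_backward(Reduce(limbseg:::ag_add, ls), seed_grad = 1 / length(ls))
    set.seed(5)
    for (nm in sample(names(model$params), 6)) {
      g <- pn[[nm]]$grad
      k <- sample(length(model$params[[nm]]), 1)
      eps <- 1e-6
      p2 <- model$params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- model$params; p3[[nm]][k] <- p3[[nm]][k] - eps
      fd <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-4,
                   info = paste(arch, nm))
    }
  }
})

test_that("training is seeded-deterministic with a full-length loss history", {
  sch <- plain_schema(1)
  set.seed(6)
  codes <- matrix(0L, 16, 8); codes[4:12, 3:6] <- 1L
  samp <- list(image = image2d(matrix(rnorm(128), 16, 8), c(1, 1)),
               mask = labelmap(codes, c(1, 1), sch))
  cfg <- train_config("unet", "desk", n_classes = 2, schema = sch,
                      input_shape = c(16, 8), depth = 2, channels = c(3L, 5L),
                      epochs = 8, batch_size = 1, seed = 11)
  f1 <- train_model(NULL, list(samp), cfg)
  f2 <- train_model(NULL, list(samp), cfg)
  expect_length(f1$history, 8)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_error(train_model(NULL, list(), cfg), "non-empty")
  # argmax of a one-hot score field reproduces exactly that labeling
  probs <- predict_probs(f1, samp$image)
  am <- apply(probs, c(1, 2), which.max) - 1L
  expect_identical(segment_image(f1, samp$image)$codes, matrix(as.integer(am), 16, 8))
})

test_that("training reduces the loss on a simple two-class problem", {
  sch <- plain_schema(1)
  set.seed(7)
  codes <- matrix(0L, 32, 16); codes[8:24, 5:12] <- 1L
  img_vals <- 0.1 + 0.7 * (codes == 1L) + matrix(rnorm(512, 0, 0.02), 32, 16)
  samp <- list(image = image2d(img_vals, c(1, 1)),
               mask = labelmap(codes, c(1, 1), sch))
  cfg <- train_config("unet", "desk", n_classes = 2, schema = sch,
                      input_shape = c(32, 16), depth = 2, channels = c(4L, 8L),
                      epochs = 40, batch_size = 1, seed = 12, flip_prob = 0)
  fit <- train_model(NULL, list(samp), cfg)
  expect_lt(fit$final_loss, fit$history[1])
  d <- dice(segment_image(fit, samp$image), samp$mask, classes = 1L)
  expect_gt(d$mean, 0.9)
})
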