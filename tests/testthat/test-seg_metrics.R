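sch2 <- plain_schema(1)

lmap <- function(codes, schema = sch2, spacing = c(1, 1))
  labelmap(codes, spacing, schema)

bin4 <- function(bits) matrix(as.integer(bits), 4, 4)  # 16 bits -> 4x4 mask

test_that("IoU and Dice match hand-counted overlap and empty-mask conventions", {
  # 4 px pred, 4 px label, 2 px overlap
  pred <- matrix(0L, 4, 4); pred[1, 1:4] <- 1L
  lab <- matrix(0L, 4, 4); lab[1, 3:4] <- 1L; lab[2, 1:2] <- 1L
  expect_equal(iou(lmap(pred), lmap(lab), 1L)$per_class[[1]], 2 / 6)
  expect_equal(dice(lmap(pred), lmap(lab), 1L)$per_class[[1]], 0.5)
  # identical maps
  expect_equal(iou(lmap(pred), lmap(pred), 1L)$mean, 1)
  expect_equal(dice(lmap(pred), lmap(pred), 1L)$mean, 1)
  # class absent from both -> 1 by convention
  z <- lmap(matrix(0L, 4, 4))
  expect_equal(iou(z, z, 1L)$per_class[[1]], 1)
  expect_equal(dice(z, z, 1L)$per_class[[1]], 1)
  # disjoint equal-size masks -> 0
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_equal(dice(lmap(a), lmap(b), 1L)$per_class[[1]], 0)
})

test_that("distance metrics match point geometry and infinity conventions", {
  a <- matrix(0L, 4, 6); a[1, 1] <- 1L
  b <- matrix(0L, 4, 6); b[1, 4] <- 1L   # 3 columns apart
  expect_equal(avg_distance(lmap(a), lmap(b), 1L)$per_class[[1]], 3)
  b5 <- matrix(0L, 4, 6); b5[1, 6] <- 1L # 5 columns apart
  expect_equal(hausdorff(lmap(a), lmap(b5), 1L)$per_class[[1]], 5)
  z <- lmap(matrix(0L, 4, 6))
  expect_equal(avg_distance(z, z, 1L)$per_class[[1]], 0)
  expect_equal(hausdorff(z, z, 1L)$per_class[[1]], 0)
  expect_equal(avg_distance(z, lmap(b), 1L)$per_class[[1]], Inf)
  expect_equal(avg_distance(lmap(b), z, 1L)$per_class[[1]], Inf)
  expect_equal(hausdorff(z, lmap(b), 1L)$per_class[[1]], Inf)
})

test_that("RAAD normalizes by label area with the stated zero-area conventions", {
  pred <- matrix(0L, 16, 16); pred[1:11, 1:10] <- 1L  # 110 px
  lab <- matrix(0L, 16, 16); lab[1:10, 1:10] <- 1L    # 100 px
  expect_equal(raad(lmap(pred), lmap(lab), 1L)$per_class[[1]], 10)
  z <- lmap(matrix(0L, 16, 16))
  expect_equal(raad(z, z, 1L)$per_class[[1]], 0)
  p5 <- matrix(0L, 16, 16); p5[1, 1:5] <- 1L
  expect_equal(raad(lmap(p5), z, 1L)$per_class[[1]], 100)
  # asymmetric: swapping pred and label changes the normalization
  expect_equal(raad(lmap(lab), lmap(pred), 1L)$per_class[[1]], 10 / 110 * 100)
})

test_that("all five metrics match the brute-force oracle on random 4x4 binary pairs", {
  set.seed(11)
  for (rep in 1:200) {
    pred <- bin4(rbinom(16, 1, runif(1)))
    lab <- bin4(rbinom(16, 1, runif(1)))
    o <- oracle_class_metrics(pred, lab, 1L)
    expect_equal(iou(lmap(pred), lmap(lab), 1L)$per_class[[1]], o[["iou"]])
    expect_equal(dice(lmap(pred), lmap(lab), 1L)$per_class[[1]], o[["dice"]])
    expect_equal(avg_distance(lmap(pred), lmap(lab), 1L)$per_class[[1]], o[["ad"]])
    expect_equal(hausdorff(lmap(pred), lmap(lab), 1L)$per_class[[1]], o[["hd"]])
    expect_equal(raad(lmap(pred), lmap(lab), 1L)$per_class[[1]], o[["raad"]])
  }
})

test_that("multiclass reports match the oracle on random 16x16 maps", {
  set.seed(12)
  sch <- plain_schema(3)
  for (rep in 1:50) {
    pred <- random_codes(16, 16, 4)
    lab <- random_codes(16, 16, 4)
    r <- evaluate_segmentation(lmap(pred, sch), lmap(lab, sch))
    o <- oracle_metrics(pred, lab, 1:3)
    expect_equal(r$per_class$iou, unname(o$per[, "iou"]))
    expect_equal(r$per_class$dice, unname(o$per[, "dice"]))
    expect_equal(r$per_class$avg_distance, unname(o$per[, "ad"]))
    expect_equal(r$per_class$hausdorff, unname(o$per[, "hd"]))
    expect_equal(r$per_class$raad_pct, unname(o$per[, "raad"]))
    expect_equal(r$weighted_raad, o$weighted_raad)
    # identities
    nonempty <- r$per_class$iou < 1 | r$per_class$dice < 1
    expect_equal(r$per_class$dice, 2 * r$per_class$iou / (1 + r$per_class$iou))
    expect_true(all(r$per_class$dice >= r$per_class$iou))
  }
})

test_that("metrics are symmetric in (pred, label) except RAAD", {
  set.seed(13)
  sch <- plain_schema(2)
  a <- lmap(random_codes(12, 12, 3), sch)
  b <- lmap(random_codes(12, 12, 3), sch)
  expect_equal(iou(a, b)$per_class, iou(b, a)$per_class)
  expect_equal(dice(a, b)$per_class, dice(b, a)$per_class)
  expect_equal(avg_distance(a, b)$per_class, avg_distance(b, a)$per_class)
  expect_equal(hausdorff(a, b)$per_class, hausdorff(b, a)$per_class)
})

test_that("removing an erroneous pred pixel never decreases that class's IoU", {
  set.seed(14)
  for (rep in 1:20) {
    lab <- bin4(rbinom(16, 1, 0.4))
    pred <- bin4(rbinom(16, 1, 0.4))
    wrong <- which(pred == 1L & lab == 0L)
    if (length(wrong) == 0) next
    before <- iou(lmap(pred), lmap(lab), 1L)$per_class[[1]]
    pred2 <- pred; pred2[wrong[1]] <- 0L
    after <- iou(lmap(pred2), lmap(lab), 1L)$per_class[[1]]
    expect_gte(after, before)
  }
})

test_that("report fields equal the standalone ops and flag infinities", {
  set.seed(15)
  sch <- plain_schema(3)
  pred <- random_codes(16, 16, 3)          # class 3 never predicted
  lab <- random_codes(16, 16, 4)
  r <- evaluate_segmentation(lmap(pred, sch), lmap(lab, sch))
  expect_equal(r$mean_iou, iou(lmap(pred, sch), lmap(lab, sch))$mean)
  expect_equal(r$mean_dice, dice(lmap(pred, sch), lmap(lab, sch))$mean)
  expect_true(r$has_infinite)
  expect_true(is.infinite(r$mean_hausdorff))
  expect_true(is.finite(r$mean_hausdorff_finite))
})

test_that("distances honor physical units when requested", {
  a <- matrix(0L, 4, 6); a[1, 1] <- 1L
  b <- matrix(0L, 4, 6); b[1, 4] <- 1L
  r <- avg_distance(lmap(a, spacing = c(0.5, 0.5)),
                    lmap(b, spacing = c(0.5, 0.5)), 1L, units = "mm")
  expect_equal(r$per_class[[1]], 1.5)
  expect_error(avg_distance(lmap(a, spacing = c(1, 2)),
                            lmap(b, spacing = c(1, 2)), 1L, units = "mm"),
               "isotropic")
})
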