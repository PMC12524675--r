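test_that("pearson handles exact linear relationships and reports r-squared", {
  x <- c(1, 2, 3, 4, 5, 6)
  p <- pearson(x, 2 * x + 1)
  expect_equal(p$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  # the r^2 reporting convention: r = 0.72 -> r^2 printed as 0.52
  set.seed(31)
  expect_equal(round(0.72^2, 2), 0.52)
  expect_error(pearson(x, rep(1, 6)), "zero variance")
  expect_error(pearson(x[1:2], x[1:2]), "3 pairs")
})

test_that("OLS matches the closed-form formulas on a hand-computed example", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  fit <- ols_fit(x, y)
  # closed-form slope/intercept
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ax <- mean(y) - bx * mean(x)
  expect_equal(fit$slope, bx)
  expect_equal(fit$intercept, ax)
  # closed-form t statistic for the slope
  res <- y - ax - bx * x
  se <- sqrt(sum(res^2) / (5 - 2) / sum((x - mean(x))^2))
  expect_equal(fit$t, bx / se)
  # noiseless slope recovery
  exact <- ols_fit(x, 0.74 * x)
  expect_equal(exact$slope, 0.74)
  expect_lt(sum(residuals(exact$fit)^2), 1e-20)
  # uncorrelated data: slope within 3 standard errors of zero
  set.seed(32)
  xs <- rnorm(500); ys <- rnorm(500)
  f <- ols_fit(xs, ys)
  expect_lt(abs(f$slope / (f$slope / f$t)), 3)
})

test_that("Bland-Altman limits are symmetric with width 2 x 1.96 x sd", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # d = -1, 0, 1; sample sd = 1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  set.seed(33)
  a <- rnorm(50); b <- rnorm(50)
  ba <- bland_altman(a, b)
  expect_equal(ba$loa_upper - ba$mean_diff, ba$mean_diff - ba$loa_lower)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * sd(a - b))
  # the midpoint of reported limits recovers the mean difference (the
  # self-consistency the published triple (-2653; -8158, 2851) satisfies
  # within 1 g of print rounding)
  expect_equal((ba$loa_upper + ba$loa_lower) / 2, ba$mean_diff)
  expect_lt(abs((-8158 + 2851) / 2 - -2653), 1)
})

test_that("paired t matches the closed form and guards zero-variance differences", {
  a <- c(5.1, 6.2, 4.8, 7.0)
  b <- c(4.9, 5.8, 5.1, 6.2)
  tt <- paired_ttest(a, b)
  d <- a - b
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(4)))
  expect_equal(tt$df, 3)
  expect_error(paired_ttest(a, a + 2), "zero-variance")
})

test_that("paired t type-I error is calibrated under the null", {
  set.seed(34)
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    a <- rnorm(20); b <- rnorm(20)
    paired_ttest(a, b)$p
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the agreement report reproduces standalone statistics and flags orphans", {
  spec <- phantom_spec(mass_noise_sd = 0, noise_sd = 0)
  cohort <- make_cohort(spec, 10, seed = 8)
  areas <- region_area_table(cohort)
  rep <- agreement_report(areas, cohort$dexa, mode = "mass")
  # noiseless link -> total-mass correlation exactly 1
  tot <- rep$correlations[rep$correlations$region == "total", ]
  expect_equal(tot$r_legs_lean_mass, 1)
  # report equals standalone ops on the same pairs
  d <- merge(areas, cohort$dexa, by = "subject_id")
  smi <- compute_smi(d$appendicular_lean_mass_g, d$height_m)
  expect_equal(rep$headline$r, pearson(d$total_muscle_cm2, smi)$r)
  est <- predict(rep$calibration, d)
  expect_equal(rep$bland_altman$mean_diff,
               bland_altman(d$legs_lean_mass_g, est)$mean_diff)
  # orphan ids are named in the error
  bad <- cohort$dexa; bad$subject_id[1] <- "ZZZ"
  expect_error(agreement_report(areas, bad), "S0001")
  # sign convention is configurable and recorded
  rev <- agreement_report(areas, cohort$dexa, mode = "mass",
                          diff_direction = "estimate_minus_dexa")
  expect_equal(rev$bland_altman$mean_diff, -rep$bland_altman$mean_diff)
  expect_equal(rev$diff_direction, "estimate_minus_dexa")
})

test_that("a cohort tuned for r = 0.7 recovers the correlation within the Fisher-z band", {
  spec <- phantom_spec()
  spec <- tune_mass_noise(spec, target_r = 0.7, n = 200, seed = 99)
  cohort <- make_cohort(spec, 200, seed = 99)
  areas <- cohort$truth[, c("subject_id", "total_muscle_cm2")]
  r <- pearson(areas$total_muscle_cm2, cohort$dexa$legs_lean_mass_g)$r
  expect_gte(r, 0.6)
  expect_lte(r, 0.8)
})

test_that("pearson is invariant to affine rescaling of either argument", {
  set.seed(35)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(10 * x + 3, y)$r, r0)
  expect_equal(pearson(x, 0.01 * y - 7)$r, r0)
  expect_equal(pearson(-x, y)$r, -r0)
})
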