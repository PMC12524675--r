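test_that("phantoms are deterministic and label every pixel", {
  spec <- phantom_spec()
  s1 <- make_phantom(spec, seed = 42)
  s2 <- make_phantom(spec, seed = 42)
  expect_identical(s1$image$values, s2$image$values)
  expect_identical(s1$mask$codes, s2$mask$codes)
  expect_identical(s1$truth, s2$truth)
  # conservation: every pixel labeled, background included
  expect_equal(sum(table(s1$mask$codes)), prod(spec$image_shape))
  # every configured region appears
  present <- unique(as.vector(s1$mask$codes))
  for (nm in names(spec$geometry_ranges))
    expect_true(limbseg:::schema_code(spec$schema, nm) %in% present)
  # intensities clipped to [0, 1]
  expect_gte(min(s1$image$values), 0)
  expect_lte(max(s1$image$values), 1)
  # different seeds differ
  expect_false(identical(s1$mask$codes, make_phantom(spec, seed = 43)$mask$codes))
})

test_that("a rectangular single-region spec yields an exact known area", {
  spec <- phantom_spec(
    image_shape = c(40, 40), pixel_spacing = c(1, 1), noise_sd = 0,
    geometry_ranges = list(medial = list(width = c(10, 10), length = c(10, 10))),
    shapes = list(medial = "rect"), legs = "left")
  s <- make_phantom(spec, seed = 1)
  expect_equal(unname(s$truth$areas_cm2["medial"]), 1)
  expect_equal(s$truth$total_muscle_cm2, 1)
})

test_that("the lean-mass noise model has the stated mean and sd", {
  spec <- phantom_spec(mass_noise_sd = 400)
  resid <- vapply(1:1000, function(i) {
    s <- make_phantom(phantom_spec(
      image_shape = c(64, 32), pixel_spacing = c(16, 16), mass_noise_sd = 400),
      seed = i)
    s$truth$legs_lean_mass_g - 35 * s$truth$total_muscle_cm2
  }, 0)
  expect_lt(abs(mean(resid)), 400 / sqrt(1000) * 4)   # ~4 standard errors
  expect_gt(sd(resid), 400 * 0.9)
  expect_lt(sd(resid), 400 * 1.1)
})

test_that("cohorts have distinct ids, matching tables, and a controllable correlation", {
  spec <- phantom_spec(mass_noise_sd = 0)
  cohort <- make_cohort(spec, 12, seed = 3)
  expect_equal(length(unique(cohort$dexa$subject_id)), 12)
  expect_equal(names(cohort$dexa),
               c("subject_id", "legs_lean_mass_g", "appendicular_lean_mass_g", "height_m"))
  # noiseless link -> correlation exactly 1
  expect_equal(cor(cohort$truth$total_muscle_cm2, cohort$dexa$legs_lean_mass_g), 1)
  # appendicular mass is the configured multiple of legs mass
  expect_equal(cohort$dexa$appendicular_lean_mass_g,
               cohort$dexa$legs_lean_mass_g * spec$arms_factor)
  # n = 1 works; n = 0 errors
  expect_equal(nrow(make_cohort(spec, 1, seed = 1)$dexa), 1)
  expect_error(make_cohort(spec, 0, seed = 1), "n must be")
})

test_that("shrinking mass noise drives the area-mass correlation monotonically to 1", {
  spec <- phantom_spec()
  rs <- vapply(c(3000, 800, 0), function(ns) {
    spec$mass_noise_sd <- ns
    cohort <- make_cohort(spec, 60, seed = 5)
    cor(cohort$truth$total_muscle_cm2, cohort$dexa$legs_lean_mass_g)
  }, 0)
  expect_true(all(diff(rs) > 0))
  expect_equal(rs[3], 1)
})

test_that("geometry too large for the image is a configuration error", {
  expect_error(make_phantom(phantom_spec(image_shape = c(32, 16)), seed = 1),
               "exceeds the image extent")
})

test_that("samples round-trip through NRRD with exact grids and spacing", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec()
  s <- make_phantom(spec, seed = 9, subject_id = "S0001")
  files <- write_sample(s, dir)
  img <- read_image_nrrd(files[["image"]])
  mask <- read_labelmap_nrrd(files[["mask"]], spec$schema)
  expect_identical(img$values, s$image$values)
  expect_equal(img$spacing, s$image$spacing)
  expect_identical(mask$codes, s$mask$codes)
  expect_equal(mask$spacing, spec$pixel_spacing)
  # three samples -> three truth rows
  write_sample(make_phantom(spec, seed = 10, subject_id = "S0002"), dir)
  write_sample(make_phantom(spec, seed = 11, subject_id = "S0003"), dir)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 3)
  expect_true(all(c("legs_lean_mass_g", "height_m", "area_medial_cm2") %in% names(truth)))
})
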