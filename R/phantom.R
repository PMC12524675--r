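# Synthetic standing lower-limb phantom: two mirrored leg silhouettes built
# from simple filled shapes (fat envelope, gluteal / lateral / medial /
# posterior / calf muscle bellies, femur + tibia + iliac bone), a class-mean
# attenuation intensity model with additive Gaussian noise, and a linear link
# from true total muscle area to a simulated legs-lean-mass record so that
# DEXA-style agreement analyses have a known ground truth.

#' Specification of the synthetic limb phantom
#'
#' Defines image geometry, the label schema, per-region size ranges (mm),
#' the intensity model, and the linear area-to-lean-mass link used to
#' simulate paired DEXA-style records.
#'
#' @param image_shape integer (rows, cols) of the rendered image.
#' @param pixel_spacing physical pixel size (row mm, col mm).
#' @param schema a [label_schema()]; regions rendered are those of the schema
#'   present in `geometry_ranges`.
#' @param geometry_ranges named list; per region a list with `width` and
#'   `length`, each a (lo, hi) range in mm sampled uniformly per phantom.
#'   Defaults cover every non-background region of the default schema.
#' @param shapes named list mapping region names to "ellipse" (default) or
#'   "rect".
#' @param intensity_means named per-class mean attenuation in \[0, 1\].
#' @param noise_sd additive Gaussian intensity noise (sd, same scale).
#' @param mass_slope g of legs lean mass per cm2 of true total muscle area.
#' @param mass_noise_sd sd (g) of the Gaussian noise on simulated lean mass.
#' @param arms_factor appendicular lean mass = legs lean mass x this factor.
#' @param height_range (lo, hi) subject height range in m, sampled uniformly.
#' @param legs which legs to render ("left", "right", or both).
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec(image_shape = c(128, 64), pixel_spacing = c(8, 8))
#' s <- make_phantom(spec, seed = 1)
#' s$truth$total_muscle_cm2
#' @export
phantom_spec <- function(image_shape = c(256, 128),
                         pixel_spacing = c(4, 4),
                         schema = default_schema(),
                         geometry_ranges = default_geometry(schema),
                         shapes = list(),
                         intensity_means = default_intensities(schema),
                         noise_sd = 0.03,
                         mass_slope = 35,
                         mass_noise_sd = 900,
                         arms_factor = 1.3,
                         height_range = c(1.45, 1.75),
                         legs = c("left", "right")) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 8))
    stop("image_shape must be two integers >= 8")
  pixel_spacing <- check_spacing(pixel_spacing)
  if (noise_sd < 0 || mass_noise_sd < 0) stop("noise sds must be >= 0")
  if (mass_slope <= 0) stop("mass_slope must be > 0")
  bad <- setdiff(names(geometry_ranges), schema$name)
  if (length(bad)) stop("geometry_ranges for unknown regions: ", paste(bad, collapse = ", "))
  for (g in geometry_ranges) {
    if (!all(c("width", "length") %in% names(g)) ||
        any(vapply(g[c("width", "length")],
                   function(r) length(r) != 2 || r[1] > r[2] || r[1] <= 0, TRUE)))
      stop("each geometry range needs positive non-empty width and length ranges")
  }
  missing_int <- setdiff(schema$name, names(intensity_means))
  if (length(missing_int))
    stop("intensity_means missing for: ", paste(missing_int, collapse = ", "))
  if (any(intensity_means < 0 | intensity_means > 1))
    stop("intensity_means must lie in [0, 1]")
  legs <- match.arg(legs, several.ok = TRUE)
  structure(list(image_shape = image_shape, pixel_spacing = pixel_spacing,
                 schema = schema, geometry_ranges = geometry_ranges,
                 shapes = shapes, intensity_means = intensity_means,
                 noise_sd = noise_sd, mass_slope = mass_slope,
                 mass_noise_sd = mass_noise_sd, arms_factor = arms_factor,
                 height_range = height_range, legs = legs),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_geometry <- function(schema = default_schema()) {
  g <- list(
    subcutaneous_fat = list(width = c(130, 160), length = c(440, 500)),
    bone             = list(width = c(20, 28),   length = c(400, 460)),
    gluteal          = list(width = c(55, 75),   length = c(80, 110)),
    lateral          = list(width = c(42, 58),   length = c(280, 340)),
    medial           = list(width = c(42, 58),   length = c(250, 320)),
    posterior        = list(width = c(60, 80),   length = c(110, 150)),
    calf             = list(width = c(60, 80),   length = c(230, 290))
  )
  g[intersect(names(g), schema$name)]
}

#' @rdname phantom_spec
#' @export
default_intensities <- function(schema = default_schema()) {
  base <- c(background = 0.05, bone = 0.90, subcutaneous_fat = 0.30,
            lateral = 0.50, medial = 0.60, posterior = 0.70,
            gluteal = 0.65, calf = 0.55)
  out <- base[schema$name]
  out[is.na(out)] <- 0.5
  names(out) <- schema$name
  out
}

# Deterministic per-sample seed stream: one 32-bit seed per (seed, index).
sample_seed <- function(seed, index) {
  as.integer((abs(as.double(seed)) * 1000003 + 7919 * as.double(index)) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

fill_shape <- function(codes, R, C, shape, r0, c0, len_px, wid_px, code) {
  if (shape == "rect") {
    nl <- max(1L, round(len_px)); nw <- max(1L, round(wid_px))
    r_lo <- max(1L, round(r0 - nl / 2)); c_lo <- max(1L, round(c0 - nw / 2))
    r_hi <- min(nrow(codes), r_lo + nl - 1L); c_hi <- min(ncol(codes), c_lo + nw - 1L)
    codes[r_lo:r_hi, c_lo:c_hi] <- code
  } else {
    a <- len_px / 2; b <- wid_px / 2
    inside <- ((R - r0) / a)^2 + ((C - c0) / b)^2 <= 1
    codes[inside] <- code
  }
  codes
}

# Anatomical layout: (row center fraction, col offset from leg axis in units
# of half thigh width, length factor, width factor, side sign applies to col
# offset so the two legs mirror).
.layout <- list(
  subcutaneous_fat = list(parts = list(
    c(rf = 0.30, off = 0.00, lf = 1.00, wf = 1.00),    # thigh envelope
    c(rf = 0.76, off = -0.10, lf = 0.80, wf = 0.80))), # calf envelope
  gluteal   = list(parts = list(c(rf = 0.10, off = 0.55, lf = 1, wf = 1))),
  lateral   = list(parts = list(c(rf = 0.30, off = 0.55, lf = 1, wf = 1))),
  medial    = list(parts = list(c(rf = 0.33, off = -0.55, lf = 1, wf = 1))),
  posterior = list(parts = list(c(rf = 0.51, off = 0.00, lf = 1, wf = 1))),
  calf      = list(parts = list(c(rf = 0.74, off = -0.10, lf = 1, wf = 1))),
  bone      = list(parts = list(
    c(rf = 0.30, off = 0.00, lf = 1.00, wf = 1.00),    # femur
    c(rf = 0.76, off = -0.10, lf = 0.75, wf = 0.60),   # tibia
    c(rf = 0.045, off = 0.30, lf = 0.16, wf = 2.2))))  # iliac blade

# Paint order: envelope first, then muscle bellies, bone on top so the femur
# and tibia shafts overwrite the posterior/calf projections they cross.
.paint_order <- c("subcutaneous_fat", "gluteal", "lateral", "medial",
                  "posterior", "calf", "bone")

#' Generate one synthetic limb phantom
#'
#' Renders the label map, the noisy intensity image, and the paired
#' DEXA-style truth record. Deterministic for fixed `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for this sample's private RNG stream.
#' @param subject_id subject identifier stored in the truth record.
#' @return A `phantom_sample` list with `image` ([image2d()]), `mask`
#'   ([labelmap()]), and `truth` (list: per-region `areas_cm2`,
#'   `total_muscle_cm2`, `legs_lean_mass_g`, `appendicular_lean_mass_g`,
#'   `height_m`, `subject_id`).
#' @export
make_phantom <- function(spec, seed, subject_id = sprintf("P%06d", seed %% 1000000L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  sp <- spec$pixel_spacing
  for (nm in names(spec$geometry_ranges)) {
    g <- spec$geometry_ranges[[nm]]
    if (g$length[2] / sp[1] > H || g$width[2] / sp[2] > W)
      stop("geometry range for '", nm, "' exceeds the image extent; ",
           "enlarge image_shape or shrink the range")
  }
  with_seed(seed, {
    R <- matrix(seq_len(H), H, W)
    C <- matrix(seq_len(W), H, W, byrow = TRUE)
    codes <- matrix(0L, H, W)
    n_legs <- length(spec$legs)
    axis_frac <- if (n_legs == 2) c(left = 0.30, right = 0.70) else c(0.40)
    # sampled region sizes (mm), shared by both legs
    dims <- lapply(spec$geometry_ranges, function(g)
      c(width = runif(1, g$width[1], g$width[2]),
        length = runif(1, g$length[1], g$length[2])))
    jitter_r <- runif(1, -0.01, 0.01) * H
    jitter_c <- runif(1, -0.01, 0.01) * W
    thigh_w <- if (!is.null(dims$subcutaneous_fat)) dims$subcutaneous_fat[["width"]] else
      max(vapply(dims, `[[`, 0, "width"))
    for (leg_i in seq_len(n_legs)) {
      side <- if (n_legs == 2 && spec$legs[leg_i] == "left") -1 else 1
      axis_c <- axis_frac[leg_i] * W + jitter_c
      for (nm in .paint_order) {
        if (is.null(dims[[nm]])) next
        shape <- if (!is.null(spec$shapes[[nm]])) spec$shapes[[nm]] else "ellipse"
        code <- schema_code(spec$schema, nm)
        for (part in .layout[[nm]]$parts) {
          r0 <- part[["rf"]] * H + jitter_r
          c0 <- axis_c + side * part[["off"]] * (thigh_w / 2) / sp[2]
          len_px <- part[["lf"]] * dims[[nm]][["length"]] / sp[1]
          wid_px <- part[["wf"]] * dims[[nm]][["width"]] / sp[2]
          codes <- fill_shape(codes, R, C, shape, r0, c0, len_px, wid_px, code)
        }
      }
    }
    mask <- labelmap(codes, sp, spec$schema)
    means <- spec$intensity_means[match(as.vector(codes), schema_code(spec$schema, names(spec$intensity_means)))]
    img_vals <- matrix(as.numeric(means), H, W)
    if (spec$noise_sd > 0)
      img_vals <- img_vals + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    img_vals <- pmin(pmax(img_vals, 0), 1)
    image <- image2d(img_vals, sp)

    areas <- region_areas_vec(mask)
    total <- sum(areas[muscle_classes(spec$schema)])
    mass <- spec$mass_slope * total +
      if (spec$mass_noise_sd > 0) rnorm(1, 0, spec$mass_noise_sd) else 0
    mass <- max(mass, .Machine$double.eps)
    height <- runif(1, spec$height_range[1], spec$height_range[2])
    truth <- list(areas_cm2 = areas, total_muscle_cm2 = total,
                  legs_lean_mass_g = mass,
                  appendicular_lean_mass_g = mass * spec$arms_factor,
                  height_m = height, subject_id = subject_id)
    structure(list(image = image, mask = mask, truth = truth),
              class = "phantom_sample")
  })
}

#' Generate a phantom cohort with a DEXA-style table
#'
#' Draws `n` phantoms with distinct subject ids, each from its own seed
#' stream derived from `(seed, index)`, and assembles the paired DEXA-style
#' table (`subject_id`, `legs_lean_mass_g`, `appendicular_lean_mass_g`,
#' `height_m`) plus a truth table of true region areas.
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects (>= 1).
#' @param seed master seed; per-sample seeds are derived from it.
#' @return A `phantom_cohort` list: `samples`, `dexa` (data frame), `truth`
#'   (data frame of true areas in cm2).
#' @export
make_cohort <- function(spec, n, seed) {
  if (n < 1) stop("n must be >= 1")
  ids <- sprintf("S%04d", seq_len(n))
  samples <- lapply(seq_len(n), function(i)
    make_phantom(spec, sample_seed(seed, i), subject_id = ids[i]))
  dexa <- data.frame(
    subject_id = ids,
    legs_lean_mass_g = vapply(samples, function(s) s$truth$legs_lean_mass_g, 0),
    appendicular_lean_mass_g = vapply(samples, function(s) s$truth$appendicular_lean_mass_g, 0),
    height_m = vapply(samples, function(s) s$truth$height_m, 0),
    stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(samples, function(s)
    data.frame(subject_id = s$truth$subject_id,
               t(s$truth$areas_cm2),
               total_muscle_cm2 = s$truth$total_muscle_cm2,
               stringsAsFactors = FALSE)))
  structure(list(samples = samples, dexa = dexa, truth = truth, spec = spec),
            class = "phantom_cohort")
}

#' Calibrate the lean-mass noise for a target area-mass correlation
#'
#' With the linear link `mass = slope * area + e`, the population correlation
#' is `1 / sqrt(1 + (sd(e) / (slope * sd(area)))^2)`, so the
#' noise sd achieving a target r is `slope * sd(area) * sqrt(1/r^2 - 1)`.
#' The area sd is estimated by rendering the cohort's masks once (mass noise
#' plays no part in the geometry).
#'
#' @param spec a [phantom_spec()].
#' @param target_r desired Pearson correlation in (0, 1].
#' @param n cohort size used both for the sd estimate and downstream.
#' @param seed master seed, as passed to [make_cohort()].
#' @return The `phantom_spec` with `mass_noise_sd` replaced.
#' @export
tune_mass_noise <- function(spec, target_r, n = 200, seed = 1) {
  if (target_r <= 0 || target_r > 1) stop("target_r must be in (0, 1]")
  areas <- vapply(seq_len(n), function(i) {
    s <- make_phantom(spec, sample_seed(seed, i))
    s$truth$total_muscle_cm2
  }, 0)
  sd_a <- sd(areas)
  spec$mass_noise_sd <- spec$mass_slope * sd_a * sqrt(1 / target_r^2 - 1)
  spec
}

#' Write a phantom sample to disk
#'
#' Writes `<id>_image.nrrd` and `<id>_mask.nrrd` (NRRD with per-axis spacing
#' in the header) and appends the truth record to `truth.csv` in the same
#' directory (created with a header on first use). Units are carried in the
#' column names.
#'
#' @param sample a `phantom_sample`.
#' @param directory output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sample <- function(sample, directory) {
  stopifnot(inherits(sample, "phantom_sample"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  id <- sample$truth$subject_id
  img_path <- file.path(directory, paste0(id, "_image.nrrd"))
  mask_path <- file.path(directory, paste0(id, "_mask.nrrd"))
  write_nrrd(sample$image$values, sample$image$spacing, img_path)
  write_nrrd(sample$mask$codes, sample$mask$spacing, mask_path)
  csv_path <- file.path(directory, "truth.csv")
  row <- data.frame(subject_id = id,
                    legs_lean_mass_g = sample$truth$legs_lean_mass_g,
                    appendicular_lean_mass_g = sample$truth$appendicular_lean_mass_g,
                    height_m = sample$truth$height_m,
                    t(sample$truth$areas_cm2),
                    total_muscle_cm2 = sample$truth$total_muscle_cm2,
                    stringsAsFactors = FALSE)
  names(row) <- sub("^(lateral|medial|posterior|gluteal|calf|bone|subcutaneous_fat)$",
                    "area_\\1_cm2", names(row))
  utils::write.table(row, csv_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv_path), append = file.exists(csv_path))
  invisible(c(image = img_path, mask = mask_path, truth = csv_path))
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s: %d x %d px, total muscle %.1f cm2, legs lean mass %.0f g\n",
              x$truth$subject_id, nrow(x$image$values), ncol(x$image$values),
              x$truth$total_muscle_cm2, x$truth$legs_lean_mass_g))
  invisible(x)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, %d x %d px\n",
              length(x$samples), x$spec$image_shape[1], x$spec$image_shape[2]))
  invisible(x)
}
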