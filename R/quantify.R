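# Label map -> physical region areas (cm2) and DEXA-comparable quantities.
# One pixel covers spacing_row x spacing_col mm2; 100 mm2 = 1 cm2.

region_areas_vec <- function(mask) {
  stopifnot(inherits(mask, "limb_labelmap"))
  px_cm2 <- mask$spacing[1] * mask$spacing[2] / 100
  cls <- mask$schema[mask$schema$code != 0L, ]
  counts <- vapply(cls$code, function(cd) sum(mask$codes == cd), 0)
  areas <- counts * px_cm2
  names(areas) <- cls$name
  areas
}

#' Physical region areas from a label map
#'
#' Converts per-class pixel counts to physical areas:
#' `area = count x spacing_row x spacing_col / 100` (mm2 to cm2). Left and
#' right instances of a region share one class code and therefore pool into
#' one bilateral area, matching the bilateral DEXA legs lean mass.
#'
#' @param mask a [labelmap()] with positive spacing.
#' @param subject_id identifier placed in the output row.
#' @return One-row data frame: `subject_id`, `area_<region>_cm2` for each
#'   muscle region of the schema, and `total_muscle_cm2` (their sum).
#' @examples
#' m <- labelmap(matrix(c(rep(0L, 156), rep(4L, 100)), 16, 16), c(1, 1))
#' region_areas(m)$total_muscle_cm2  # 100 px at 1 mm -> 1 cm2
#' @export
region_areas <- function(mask, subject_id = "subject") {
  areas <- region_areas_vec(mask)
  mus <- muscle_classes(mask$schema)
  out <- data.frame(subject_id = subject_id, t(areas[mus]),
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("area_", mus, "_cm2")
  out$total_muscle_cm2 <- sum(areas[mus])
  out
}

#' Region-area table for a set of masks
#'
#' @param masks named list of [labelmap()]s (names become subject ids) or a
#'   `phantom_cohort`.
#' @return Data frame with one [region_areas()] row per mask.
#' @export
region_area_table <- function(masks) {
  if (inherits(masks, "phantom_cohort"))
    masks <- stats::setNames(lapply(masks$samples, `[[`, "mask"),
                             vapply(masks$samples, function(s) s$truth$subject_id, ""))
  ids <- names(masks)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(masks))
  do.call(rbind, Map(region_areas, masks, ids))
}

#' Skeletal muscle index (SMI)
#'
#' SMI is the appendicular lean mass (arms + legs) in kg divided by the
#' square of the subject's height: `smi = (mass_g / 1000) / height_m^2`,
#' in kg/m2.
#'
#' @param appendicular_lean_mass_g appendicular lean mass in grams (vectorized).
#' @param height_m height in meters, > 0.
#' @return SMI in kg/m2.
#' @examples
#' compute_smi(16000, 1.6)  # 6.25 kg/m2
#' @export
compute_smi <- function(appendicular_lean_mass_g, height_m) {
  if (any(height_m <= 0)) stop("height must be > 0")
  if (any(appendicular_lean_mass_g < 0)) stop("lean mass must be >= 0")
  (appendicular_lean_mass_g / 1000) / height_m^2
}

#' Percent change between two measurements
#'
#' `100 * (after - before) / before`, reported to one decimal place, the
#' convention used when tracking follow-up SMI or muscle-area changes.
#'
#' @param before baseline value, nonzero.
#' @param after follow-up value.
#' @return Percent change rounded to one decimal.
#' @examples
#' percent_change(5.15, 6.31)  # +22.5
#' percent_change(77, 71.5)    # -7.1
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("before must be nonzero")
  round(100 * (after - before) / before, 1)
}

#' Calibrate areas to lean mass
#'
#' Ordinary least squares of DEXA legs lean mass (g) on total muscle area
#' (cm2), giving the linear map used to express segmentation output on the
#' grams scale for Bland-Altman analysis.
#'
#' @param areas data frame from [region_area_table()] (needs `subject_id`,
#'   `total_muscle_cm2`).
#' @param dexa data frame with `subject_id` and `legs_lean_mass_g`.
#' @return A `calibration_model`: `slope` (g/cm2), `intercept` (g), `fit`
#'   (the `lm`), `n`.
#' @export
fit_calibration <- function(areas, dexa) {
  d <- merge(areas, dexa, by = "subject_id")
  if (nrow(d) < 3) stop("calibration needs at least 3 paired subjects")
  fit <- lm(legs_lean_mass_g ~ total_muscle_cm2, data = d)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 fit = fit, n = nrow(d)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> mass_g = %.4g * area_cm2 + %.4g  (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  area <- if (is.data.frame(newdata)) newdata$total_muscle_cm2 else newdata
  object$slope * area + object$intercept
}
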