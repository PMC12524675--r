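# Multiclass segmentation evaluation. Each class is binarized out of the two
# label maps and compared with five metrics:
#   IoU        |A & B| / |A | B|          (empty union -> 1)
#   Dice       2|A & B| / (|A| + |B|)     (both empty -> 1)
#   AvgDist    (mean dist A->B + mean dist B->A) / 2, via the exact Euclidean
#              distance transform of the mask complements
#              (both empty -> 0, exactly one empty -> +Inf)
#   RAAD       |areaA - areaB| / areaB * 100%  (label empty -> 0 or 100)
#   Hausdorff  max(directed(A->B), directed(B->A)) on full pixel coordinate
#              sets (both empty -> 0, one empty -> +Inf)
# Distances are in pixel units by default; with units = "mm" the (isotropic)
# spacing is applied.

check_metric_args <- function(pred, label) {
  stopifnot(inherits(pred, "limb_labelmap"), inherits(label, "limb_labelmap"))
  if (!same_grid(pred, label)) stop("pred and label shapes differ")
  if (!isTRUE(all.equal(pred$spacing, label$spacing)))
    stop("pred and label spacings differ")
}

default_metric_classes <- function(label, include_background = FALSE) {
  sch <- label$schema
  if (include_background) sch$code else sch$code[sch$code != 0L]
}

# distance (in pixels) from every pixel to the nearest TRUE pixel of m;
# exact Euclidean via the distance transform of the complement
dist_to_set <- function(m) {
  EBImage::distmap(!m, metric = "euclidean")
}

#' Per-class intersection over union
#'
#' `IoU_c = |pred & label| / |pred | label|` per class, with the empty-union
#' convention `IoU_c = 1` (a class absent from both maps is a perfect match).
#' The mean is the unweighted average over the evaluated classes.
#'
#' @param pred,label [labelmap()]s on the same grid with the same spacing.
#' @param classes integer class codes to evaluate; defaults to all
#'   non-background codes of the label schema.
#' @return List with `per_class` (named numeric) and `mean`.
#' @export
iou <- function(pred, label, classes = default_metric_classes(label)) {
  check_metric_args(pred, label)
  per <- vapply(classes, function(cd) {
    p <- pred$codes == cd; l <- label$codes == cd
    u <- sum(p | l)
    if (u == 0) 1 else sum(p & l) / u
  }, 0)
  names(per) <- class_names_for(label$schema, classes)
  list(per_class = per, mean = mean(per))
}

#' Per-class Dice coefficient
#'
#' `Dice_c = 2 |pred & label| / (|pred| + |label|)`; when both masks are
#' empty the Dice is 1, consistent with the IoU convention and the identity
#' `Dice = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou
#' @return List with `per_class` and `mean`.
#' @export
dice <- function(pred, label, classes = default_metric_classes(label)) {
  check_metric_args(pred, label)
  per <- vapply(classes, function(cd) {
    p <- pred$codes == cd; l <- label$codes == cd
    s <- sum(p) + sum(l)
    if (s == 0) 1 else 2 * sum(p & l) / s
  }, 0)
  names(per) <- class_names_for(label$schema, classes)
  list(per_class = per, mean = mean(per))
}

#' Per-class symmetric average distance
#'
#' For each class, the mean Euclidean distance from every predicted pixel to
#' the nearest label pixel and vice versa, averaged:
#' `(mean(pred -> label) + mean(label -> pred)) / 2`. Both masks empty gives
#' 0; exactly one empty gives `+Inf`.
#'
#' @inheritParams iou
#' @param units "pixel" (default) or "mm"; "mm" requires isotropic spacing.
#' @return List with `per_class`, `mean` (infinities propagated), and
#'   `mean_finite` (infinite classes excluded; `NaN` if none finite).
#' @export
avg_distance <- function(pred, label, classes = default_metric_classes(label),
                         units = c("pixel", "mm")) {
  check_metric_args(pred, label)
  units <- match.arg(units)
  scale <- dist_scale(label, units)
  per <- vapply(classes, function(cd) {
    p <- pred$codes == cd; l <- label$codes == cd
    np <- sum(p); nl <- sum(l)
    if (np == 0 && nl == 0) return(0)
    if (np == 0 || nl == 0) return(Inf)
    dl <- dist_to_set(l); dp <- dist_to_set(p)
    (mean(dl[p]) + mean(dp[l])) / 2 * scale
  }, 0)
  names(per) <- class_names_for(label$schema, classes)
  list(per_class = per, mean = mean(per), mean_finite = finite_mean(per))
}

#' Per-class Hausdorff distance
#'
#' The maximum of the two directed Hausdorff distances between the full
#' per-class pixel coordinate sets (not boundary-only). Both masks empty
#' gives 0; exactly one empty gives `+Inf`.
#'
#' @inheritParams avg_distance
#' @return List with `per_class`, `mean`, and `mean_finite`.
#' @export
hausdorff <- function(pred, label, classes = default_metric_classes(label),
                      units = c("pixel", "mm")) {
  check_metric_args(pred, label)
  units <- match.arg(units)
  scale <- dist_scale(label, units)
  per <- vapply(classes, function(cd) {
    p <- pred$codes == cd; l <- label$codes == cd
    np <- sum(p); nl <- sum(l)
    if (np == 0 && nl == 0) return(0)
    if (np == 0 || nl == 0) return(Inf)
    dl <- dist_to_set(l); dp <- dist_to_set(p)
    max(max(dl[p]), max(dp[l])) * scale
  }, 0)
  names(per) <- class_names_for(label$schema, classes)
  list(per_class = per, mean = mean(per), mean_finite = finite_mean(per))
}

#' Per-class relative absolute area difference (RAAD)
#'
#' `|pred_area - label_area| / label_area x 100%` per class. A class with
#' zero label area scores 0 if the prediction is also empty, 100 otherwise.
#' The aggregate is a weighted average with weights proportional to the
#' label class areas (classes the label does not contain get weight 0);
#' RAAD is therefore not symmetric in (pred, label).
#'
#' @inheritParams iou
#' @return List with `per_class` (percent) and `weighted_mean`.
#' @export
raad <- function(pred, label, classes = default_metric_classes(label)) {
  check_metric_args(pred, label)
  pa <- vapply(classes, function(cd) sum(pred$codes == cd), 0)
  la <- vapply(classes, function(cd) sum(label$codes == cd), 0)
  per <- ifelse(la > 0, abs(pa - la) / la * 100, ifelse(pa == 0, 0, 100))
  names(per) <- class_names_for(label$schema, classes)
  w <- if (sum(la) > 0) la / sum(la) else rep(0, length(la))
  list(per_class = per, weighted_mean = sum(per * w))
}

#' Full multiclass metric report
#'
#' Evaluates all five metrics and assembles a `metric_report`: a per-class
#' table plus the class means (IoU, Dice, average distance, Hausdorff, both
#' with infinities propagated and with infinite classes excluded) and the
#' area-weighted RAAD.
#'
#' @inheritParams avg_distance
#' @param include_background include code 0 in the evaluated classes
#'   (default FALSE).
#' @return A `metric_report` list: `per_class` data frame, `mean_iou`,
#'   `mean_dice`, `mean_avg_distance`, `mean_hausdorff`,
#'   `mean_avg_distance_finite`, `mean_hausdorff_finite`, `weighted_raad`,
#'   `has_infinite`, `classes`, `n_classes`, `units`.
#' @examples
#' m <- labelmap(matrix(c(rep(0L, 252), rep(4L, 4)), 16, 16), c(1, 1))
#' evaluate_segmentation(m, m)$mean_dice  # perfect prediction -> 1
#' @export
evaluate_segmentation <- function(pred, label,
                                  classes = default_metric_classes(label, include_background),
                                  include_background = FALSE,
                                  units = c("pixel", "mm")) {
  units <- match.arg(units)
  i <- iou(pred, label, classes)
  d <- dice(pred, label, classes)
  a <- avg_distance(pred, label, classes, units)
  h <- hausdorff(pred, label, classes, units)
  r <- raad(pred, label, classes)
  per <- data.frame(class = names(i$per_class), code = classes,
                    iou = i$per_class, dice = d$per_class,
                    avg_distance = a$per_class, hausdorff = h$per_class,
                    raad_pct = r$per_class, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(per_class = per,
                 mean_iou = i$mean, mean_dice = d$mean,
                 mean_avg_distance = a$mean, mean_hausdorff = h$mean,
                 mean_avg_distance_finite = a$mean_finite,
                 mean_hausdorff_finite = h$mean_finite,
                 weighted_raad = r$weighted_mean,
                 has_infinite = any(!is.finite(c(a$per_class, h$per_class))),
                 classes = classes, n_classes = length(classes),
                 units = units),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_report> %d classes, distances in %s\n", x$n_classes, x$units))
  print(cbind(x$per_class[1], round(x$per_class[-1], digits)), row.names = FALSE)
  cat(sprintf("means: IoU %.4f | Dice %.4f | AD %.4g | HD %.4g | weighted RAAD %.4g%%\n",
              x$mean_iou, x$mean_dice, x$mean_avg_distance, x$mean_hausdorff,
              x$weighted_raad))
  if (x$has_infinite)
    cat(sprintf("  (infinite distances present; finite-only means: AD %.4g | HD %.4g)\n",
                x$mean_avg_distance_finite, x$mean_hausdorff_finite))
  invisible(x)
}

#' Write a metric report as CSV
#'
#' One row per class plus a `mean` row (unweighted means; RAAD area-weighted).
#'
#' @param report a `metric_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  per <- report$per_class
  mean_row <- data.frame(class = "mean", code = NA_integer_,
                         iou = report$mean_iou, dice = report$mean_dice,
                         avg_distance = report$mean_avg_distance,
                         hausdorff = report$mean_hausdorff,
                         raad_pct = report$weighted_raad,
                         stringsAsFactors = FALSE)
  write.csv(rbind(per, mean_row), path, row.names = FALSE)
  invisible(path)
}

class_names_for <- function(schema, classes) {
  nm <- schema$name[match(classes, schema$code)]
  ifelse(is.na(nm), paste0("code_", classes), nm)
}

finite_mean <- function(x) {
  f <- x[is.finite(x)]
  if (length(f) == 0) NaN else mean(f)
}

dist_scale <- function(label, units) {
  if (units == "pixel") return(1)
  if (abs(label$spacing[1] - label$spacing[2]) > 1e-12)
    stop("units = 'mm' requires isotropic pixel spacing")
  label$spacing[1]
}
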