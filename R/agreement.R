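# Method-agreement machinery between segmentation-derived areas and
# DEXA-derived indices: Pearson correlation (per region x index matrix),
# ordinary least squares, Bland-Altman limits of agreement, paired t-tests.
# Standard fits go through stats (cor.test, lm, t.test); the wrappers fix
# the reporting conventions (two-sided p, r^2 to two decimals, 1.96 x sample
# sd limits).

#' Pearson correlation with two-sided p and r-squared
#'
#' @param x,y paired numeric vectors, n >= 3, finite, nonzero variance.
#' @return List: `r`, `p` (two-sided), `r_squared` (rounded to two decimals,
#'   the convention for reporting explained variance), `n`.
#' @examples
#' pearson(1:10, 2 * (1:10) + 1)$r  # exactly 1
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, r_squared = round(r^2, 2), n = length(x))
}

#' Ordinary least squares of y on x
#'
#' @param x predictor vector, non-degenerate.
#' @param y response vector.
#' @return List: `slope`, `intercept`, `t` (slope != 0), `p`, `n`, `fit`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0) stop("degenerate predictor: zero variance")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))$coefficients  # exact fits are legitimate
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       t = s["x", "t value"], p = s["x", "Pr(>|t|)"], n = length(x), fit = fit)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; mean difference and 95% limits of agreement
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation. The
#' limits are symmetric about the mean difference by construction, with
#' width `2 x 1.96 x sd(d)`.
#'
#' @param a,b paired measurement vectors (method A, method B), n >= 2.
#' @return List: `mean_diff`, `loa_lower`, `loa_upper`, `sd_diff`, `n`,
#'   `differences`, `means` (per-pair averages, the conventional x axis).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       sd_diff = s, n = length(d), differences = d, means = (a + b) / 2)
}

#' Bland-Altman plot
#'
#' @param ba result of [bland_altman()].
#' @param xlab,ylab,main usual plot annotations.
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, xlab = "mean of methods",
                              ylab = "difference", main = "Bland-Altman") {
  plot(ba$means, ba$differences, xlab = xlab, ylab = ylab, main = main, pch = 19)
  abline(h = ba$mean_diff, col = "red", lty = 2)
  abline(h = c(ba$loa_lower, ba$loa_upper), col = "black", lty = 2)
  invisible(ba)
}

#' Two-sided paired t-test
#'
#' @param a,b paired vectors, n >= 2; the differences must have nonzero
#'   variance (a pure constant shift has no finite t statistic).
#' @return List: `t`, `p` (two-sided), `mean_diff`, `df`, `n`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (sd(d) <= sqrt(.Machine$double.eps) * max(1, abs(mean(d))))
    stop("paired t undefined: zero-variance differences")
  tt <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter), n = length(a))
}

#' Full agreement report between region areas and DEXA records
#'
#' Matches the two tables on `subject_id` and emits, in the layout of a
#' region-by-index correlation table: Pearson r and two-sided p for every
#' muscle region (plus the total) against both the skeletal muscle index and
#' the legs lean mass; an OLS fit of legs lean mass on the estimated
#' quantity; a Bland-Altman analysis; and paired t-tests. In `mode = "mass"`
#' the segmentation estimate enters on the grams scale via the supplied (or
#' internally fitted) calibration; in `mode = "area"` the raw cm2 areas are
#' used and Bland-Altman/paired-t (which need a common scale) are computed on
#' the calibrated values only.
#'
#' @param areas data frame from [region_area_table()].
#' @param dexa data frame with `subject_id`, `legs_lean_mass_g`,
#'   `appendicular_lean_mass_g`, `height_m`.
#' @param calibration optional [fit_calibration()] model; fitted on the
#'   matched pairs when absent.
#' @param mode "area" or "mass" (see above).
#' @param diff_direction Bland-Altman sign convention: "dexa_minus_estimate"
#'   (default) or "estimate_minus_dexa". The chosen direction is recorded in
#'   the report.
#' @return An `agreement_report` list: `correlations` (data frame region x
#'   index), `headline` (total vs SMI: r, p, r_squared), `ols`,
#'   `bland_altman`, `paired_t_mass`, `calibration`, `mode`,
#'   `diff_direction`, `n`.
#' @export
agreement_report <- function(areas, dexa, calibration = NULL,
                             mode = c("area", "mass"),
                             diff_direction = c("dexa_minus_estimate",
                                                "estimate_minus_dexa")) {
  mode <- match.arg(mode)
  diff_direction <- match.arg(diff_direction)
  need <- c("subject_id", "legs_lean_mass_g", "appendicular_lean_mass_g", "height_m")
  if (!all(need %in% names(dexa)))
    stop("dexa table missing columns: ", paste(setdiff(need, names(dexa)), collapse = ", "))
  orphans <- c(setdiff(areas$subject_id, dexa$subject_id),
               setdiff(dexa$subject_id, areas$subject_id))
  if (length(orphans))
    stop("unmatched subject ids: ", paste(unique(orphans), collapse = ", "))
  d <- merge(areas, dexa, by = "subject_id")
  if (nrow(d) < 3) stop("need at least 3 matched subjects")
  d$smi <- compute_smi(d$appendicular_lean_mass_g, d$height_m)

  region_cols <- c(grep("^area_.*_cm2$", names(d), value = TRUE), "total_muscle_cm2")
  region_names <- sub("^area_(.*)_cm2$", "\\1", region_cols)
  region_names[region_cols == "total_muscle_cm2"] <- "total"
  cor_rows <- lapply(seq_along(region_cols), function(i) {
    x <- d[[region_cols[i]]]
    degen <- sd(x) == 0
    p_smi <- if (degen) list(r = NA_real_, p = NA_real_) else pearson(x, d$smi)
    p_llm <- if (degen) list(r = NA_real_, p = NA_real_) else pearson(x, d$legs_lean_mass_g)
    data.frame(region = region_names[i],
               r_smi = p_smi$r, p_smi = p_smi$p,
               r_legs_lean_mass = p_llm$r, p_legs_lean_mass = p_llm$p,
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, cor_rows)
  # degenerate estimates (e.g. an untrained model predicting one class
  # everywhere) yield NA statistics rather than aborting the report
  headline <- tryCatch(pearson(d$total_muscle_cm2, d$smi),
                       error = function(e) list(r = NA_real_, p = NA_real_,
                                                r_squared = NA_real_, n = nrow(d)))
  if (is.null(calibration)) calibration <- fit_calibration(areas, dexa)
  est_mass <- predict(calibration, d)
  estimate <- if (mode == "mass") est_mass else d$total_muscle_cm2
  ols <- tryCatch(ols_fit(estimate, d$legs_lean_mass_g),
                  error = function(e) NULL)
  ba_pair <- if (diff_direction == "dexa_minus_estimate")
    list(a = d$legs_lean_mass_g, b = est_mass) else
    list(a = est_mass, b = d$legs_lean_mass_g)
  ba <- bland_altman(ba_pair$a, ba_pair$b)
  pt <- tryCatch(paired_ttest(est_mass, d$legs_lean_mass_g),
                 error = function(e) NULL)

  structure(list(correlations = correlations, headline = headline,
                 ols = ols, bland_altman = ba, paired_t_mass = pt,
                 calibration = calibration, mode = mode,
                 diff_direction = diff_direction, n = nrow(d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs, mode = %s\n", x$n, x$mode))
  tab <- x$correlations
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("headline (total vs SMI): r = %.2f (p = %.3g), r^2 = %.2f\n",
              x$headline$r, x$headline$p, x$headline$r_squared))
  if (!is.null(x$ols))
    cat(sprintf("OLS legs lean mass ~ estimate: slope %.3g (t = %.2f, p = %.3g)\n",
                x$ols$slope, x$ols$t, x$ols$p))
  cat(sprintf("Bland-Altman (%s): mean diff %.1f, 95%% LoA [%.1f, %.1f] g\n",
              x$diff_direction, x$bland_altman$mean_diff,
              x$bland_altman$loa_lower, x$bland_altman$loa_upper))
  if (!is.null(x$paired_t_mass))
    cat(sprintf("paired t (estimate vs legs lean mass): t = %.2f, p = %.3g\n",
                x$paired_t_mass$t, x$paired_t_mass$p))
  invisible(x)
}

#' Write an agreement report as CSV
#'
#' The region-by-index correlation table plus rows for the OLS fit,
#' Bland-Altman triple, and paired t-test.
#'
#' @param report an `agreement_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  cor_tab <- report$correlations
  cor_tab$statistic <- "pearson"
  extra <- data.frame(
    region = c("total", "total", "total", "total", "total"),
    r_smi = NA_real_, p_smi = NA_real_,
    r_legs_lean_mass = c(if (is.null(report$ols)) NA_real_ else report$ols$slope,
                         report$bland_altman$mean_diff,
                         report$bland_altman$loa_lower, report$bland_altman$loa_upper,
                         if (is.null(report$paired_t_mass)) NA_real_ else report$paired_t_mass$t),
    p_legs_lean_mass = c(if (is.null(report$ols)) NA_real_ else report$ols$p, NA, NA, NA,
                         if (is.null(report$paired_t_mass)) NA_real_ else report$paired_t_mass$p),
    statistic = c("ols_slope", "ba_mean_diff_g", "ba_loa_lower_g",
                  "ba_loa_upper_g", "paired_t"),
    stringsAsFactors = FALSE)
  write.csv(rbind(cor_tab, extra), path, row.names = FALSE)
  invisible(path)
}
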