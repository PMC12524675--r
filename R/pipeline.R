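# End-to-end pipeline: simulate -> preprocess -> train -> predict ->
# evaluate -> quantify -> agree, under one global seed, with a run manifest
# (config + seed + versions) and a stage log so any run can be reproduced.

#' Pipeline configuration
#'
#' One source of truth for a full run. All randomness (phantom geometry,
#' lean-mass noise, weight init, shuffling, augmentation, the subject-level
#' train/validation split) derives from `seed`.
#'
#' @param out_dir artifact directory.
#' @param n number of phantom subjects.
#' @param seed global seed.
#' @param spec a [phantom_spec()].
#' @param pre a [preprocess_config()].
#' @param train a [train_config()].
#' @param val_fraction subject fraction held out for validation (split is
#'   by subject, seeded).
#' @param target_r if non-NULL, [tune_mass_noise()] is applied first so the
#'   cohort's area-mass correlation targets this value.
#' @param agreement_mode "mass" or "area", see [agreement_report()].
#' @param log_level "info" or "quiet".
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, n = 20, seed = 1,
                            spec = phantom_spec(), pre = preprocess_config(),
                            train = train_config(), val_fraction = 0.2,
                            target_r = NULL, agreement_mode = c("mass", "area"),
                            log_level = c("info", "quiet")) {
  if (n < 2) stop("pipeline needs n >= 2 subjects")
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction must be in (0, 1)")
  structure(list(out_dir = out_dir, n = as.integer(n), seed = as.integer(seed),
                 spec = spec, pre = pre, train = train,
                 val_fraction = val_fraction, target_r = target_r,
                 agreement_mode = match.arg(agreement_mode),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `out_dir`, `n_subjects`, `seed`, `val_fraction`,
#' `target_r`, `agreement_mode`, `log_level`, and the nested sections
#' `phantom`, `preprocess`, `train` whose keys mirror the corresponding
#' constructor arguments (`phantom` additionally accepts `n_muscles`; the
#' subject count is spelled `n_subjects` because a bare `n` is a YAML 1.1
#' boolean). Unknown keys are an error before any stage runs.
#'
#' @param path YAML file path.
#' @param out_dir override for the artifact directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  top_ok <- c("out_dir", "n_subjects", "seed", "val_fraction", "target_r",
              "agreement_mode", "log_level", "phantom", "preprocess", "train")
  bad <- setdiff(names(y), top_ok)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  ph <- y$phantom %||% list()
  if (!is.null(ph$n_muscles)) {
    ph$schema <- default_schema(ph$n_muscles); ph$n_muscles <- NULL
  }
  check_args <- function(given, fn, section) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) stop("unknown ", section, " config keys: ", paste(bad, collapse = ", "))
    given
  }
  spec <- do.call(phantom_spec, check_args(ph, phantom_spec, "phantom"))
  pre <- do.call(preprocess_config, check_args(y$preprocess %||% list(),
                                               preprocess_config, "preprocess"))
  tr <- y$train %||% list()
  tr$schema <- spec$schema
  tr$n_classes <- nrow(spec$schema)
  train <- do.call(train_config, check_args(tr, train_config, "train"))
  args <- y[intersect(names(y), c("seed", "val_fraction", "target_r",
                                  "agreement_mode", "log_level"))]
  if (!is.null(y$n_subjects)) args$n <- y$n_subjects
  args$out_dir <- out_dir %||% y$out_dir %||% stop("config must set out_dir")
  args$spec <- spec; args$pre <- pre; args$train <- train
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(cfg, con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  if (cfg$log_level != "quiet") message(msg)
  writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, train, predict, evaluate, quantify, and
#' agree in order, writing every stage's artifacts (NRRD samples, truth and
#' DEXA CSVs, training log, per-image and aggregate metric CSVs, area table,
#' agreement report) plus `manifest.json` and `run.log` under
#' `cfg$out_dir`. A rerun with the same config reproduces the deterministic
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the fitted model, per-image metric
#'   reports, the aggregate metric row, the area table, the agreement
#'   report, and the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$out_dir, "run.log"), "wt")
  on.exit(close(logf))
  spec <- cfg$spec
  if (!is.null(cfg$target_r)) {
    spec <- tune_mass_noise(spec, cfg$target_r, n = cfg$n, seed = cfg$seed)
    pipe_log(cfg, logf, "simulate: tuned mass_noise_sd = ", signif(spec$mass_noise_sd, 4),
             " for target r = ", cfg$target_r)
  }
  pipe_log(cfg, logf, "simulate: ", cfg$n, " phantoms, seed ", cfg$seed)
  cohort <- make_cohort(spec, cfg$n, cfg$seed)
  data_dir <- file.path(cfg$out_dir, "data")
  for (s in cohort$samples) write_sample(s, data_dir)
  write.csv(cohort$dexa, file.path(cfg$out_dir, "dexa.csv"), row.names = FALSE)

  pipe_log(cfg, logf, "preprocess: pipeline + resize to (",
           paste(cfg$train$input_shape, collapse = ", "), ")")
  prepared <- lapply(cohort$samples, prepare_sample, cfg = cfg$train, pre = cfg$pre)

  n_val <- max(1L, round(cfg$val_fraction * cfg$n))
  split <- with_seed(cfg$seed, sample.int(cfg$n))
  val_idx <- split[seq_len(n_val)]
  train_idx <- setdiff(split, val_idx)
  pipe_log(cfg, logf, "split: ", length(train_idx), " training / ", n_val,
           " validation subjects (by subject, seeded)")

  pipe_log(cfg, logf, "train: ", cfg$train$arch, " (", cfg$train$profile,
           " profile), ", cfg$train$epochs, " epochs")
  fit <- train_model(NULL, prepared[train_idx], cfg$train)
  write.csv(data.frame(epoch = seq_along(fit$history), dice_loss = fit$history),
            file.path(cfg$out_dir, "training_log.csv"), row.names = FALSE)
  save_model(fit, file.path(cfg$out_dir, "model"))

  pipe_log(cfg, logf, "predict + evaluate: ", n_val, " validation images")
  reports <- lapply(val_idx, function(i) {
    pred <- segment_image(fit, prepared[[i]]$image)
    evaluate_segmentation(pred, prepared[[i]]$mask)
  })
  agg <- data.frame(
    mean_iou = mean(vapply(reports, `[[`, 0, "mean_iou")),
    mean_dice = mean(vapply(reports, `[[`, 0, "mean_dice")),
    mean_avg_distance = mean(vapply(reports, `[[`, 0, "mean_avg_distance_finite")),
    mean_hausdorff = mean(vapply(reports, `[[`, 0, "mean_hausdorff_finite")),
    weighted_raad = mean(vapply(reports, `[[`, 0, "weighted_raad")))
  write.csv(agg, file.path(cfg$out_dir, "validation_metrics.csv"), row.names = FALSE)

  pipe_log(cfg, logf, "quantify: region areas from predicted masks, all subjects")
  pred_masks <- lapply(prepared, function(p) segment_image(fit, p$image))
  names(pred_masks) <- cohort$dexa$subject_id
  areas <- region_area_table(pred_masks)
  write.csv(areas, file.path(cfg$out_dir, "areas.csv"), row.names = FALSE)

  pipe_log(cfg, logf, "agree: mode = ", cfg$agreement_mode)
  agree <- agreement_report(areas, cohort$dexa, mode = cfg$agreement_mode)
  write_agreement_report(agree, file.path(cfg$out_dir, "agreement.csv"))

  manifest <- list(seed = cfg$seed, n = cfg$n,
                   package_version = as.character(utils::packageVersion("limbseg")),
                   r_version = R.version.string,
                   train = cfg$train[c("arch", "profile", "learning_rate",
                                       "weight_decay", "batch_size", "epochs",
                                       "input_shape", "depth", "channels")],
                   phantom = spec[c("image_shape", "pixel_spacing", "noise_sd",
                                    "mass_slope", "mass_noise_sd")],
                   agreement_mode = cfg$agreement_mode,
                   validation_subjects = cohort$dexa$subject_id[val_idx])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(cfg, logf, "done: artifacts in ", cfg$out_dir)
  invisible(list(fit = fit, reports = reports, metrics = agg, areas = areas,
                 agreement = agree, out_dir = cfg$out_dir))
}

#' Save / load a model checkpoint directory
#'
#' The checkpoint is plain text: a YAML snapshot of the training
#' configuration and a JSON dump of the parameter arrays.
#'
#' @param fit a `limbseg_fit` or `limbseg_model`.
#' @param dir checkpoint directory.
#' @return `dir` (save) or a `limbseg_model` (load).
#' @export
save_model <- function(fit, dir) {
  model <- if (inherits(fit, "limbseg_fit")) fit$model else fit
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$cfg
  snap <- cfg[c("arch", "profile", "n_classes", "learning_rate", "weight_decay",
                "batch_size", "epochs", "seed", "input_shape", "depth",
                "channels", "deep_supervision", "flip_prob", "include_background",
                "ce_weight")]
  snap$schema_names <- cfg$schema$name
  snap$schema_codes <- cfg$schema$code
  snap$schema_muscle <- cfg$schema$muscle
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  dims <- lapply(model$params, function(p) dim(p) %||% length(p))
  jsonlite::write_json(list(dims = dims, values = lapply(model$params, as.vector)),
                       file.path(dir, "params.json"), auto_unbox = FALSE, digits = NA)
  if (inherits(fit, "limbseg_fit"))
    write.csv(data.frame(epoch = seq_along(fit$history), dice_loss = fit$history),
              file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  snap <- yaml::read_yaml(file.path(dir, "config.yaml"))
  schema <- label_schema(unlist(snap$schema_names), unlist(snap$schema_codes),
                         unlist(snap$schema_muscle))
  cfg <- train_config(arch = snap$arch, profile = snap$profile,
                      n_classes = snap$n_classes, schema = schema,
                      learning_rate = snap$learning_rate,
                      weight_decay = snap$weight_decay,
                      batch_size = snap$batch_size, epochs = snap$epochs,
                      seed = snap$seed, input_shape = unlist(snap$input_shape),
                      depth = snap$depth, channels = unlist(snap$channels),
                      deep_supervision = snap$deep_supervision,
                      flip_prob = snap$flip_prob,
                      include_background = snap$include_background,
                      ce_weight = snap$ce_weight)
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- Map(function(v, d) if (length(d) == 2) matrix(v, d[1], d[2]) else as.numeric(v),
                pj$values, pj$dims)
  model <- build_model(cfg)
  stopifnot(identical(names(model$params), names(params)))
  model$params <- params
  model$trained <- TRUE
  model
}
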