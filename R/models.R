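# Segmentation networks: U-Net (maxpool encoder, skip connections), a 2D
# V-Net adaptation (residual blocks, strided-convolution downsampling), and
# U-Net++ (nested dense skip pathways with optional deep supervision). All
# three share the soft Dice training loss and the AdamW optimizer.

#' Training configuration
#'
#' Two profiles are provided. `"paper"` carries the reference hyperparameters
#' for full-scale GPU training: learning rate 8e-5, weight decay 1e-5, batch
#' size 8, 3000 epochs, 512 x 1024 inputs. `"desk"` is the package's
#' CPU-scale profile used throughout the examples and tests: 128 x 64
#' portrait inputs, thin channels (level-0 width 16), 50 epochs, batch size
#' 2, and learning rate 3e-3, appropriate for a small instance-normalized
#' network trained from scratch for tens of epochs rather than fine-tuned
#' for thousands.
#'
#' @param arch "unet", "vnet2d", or "unetpp".
#' @param profile "desk" or "paper"; sets the defaults below.
#' @param n_classes number of classes including background (>= 2).
#' @param schema [label_schema()] the class channels follow (row i of the
#'   schema is channel i).
#' @param learning_rate,weight_decay,batch_size,epochs AdamW settings.
#' @param seed integer seed governing initialization, shuffling, and
#'   augmentation.
#' @param input_shape (rows, cols) the network expects; must be divisible by
#'   `2^(depth-1)`.
#' @param depth number of resolution levels.
#' @param channels feature widths per level (length `depth`).
#' @param deep_supervision U-Net++ only: average the Dice loss over all
#'   nested decoder heads.
#' @param flip_prob training-time horizontal-flip augmentation probability.
#' @param include_background include the background channel in the Dice loss.
#' @param ce_weight weight of an optional auxiliary cross-entropy term added
#'   to the soft Dice training objective (`loss = dice + ce_weight * CE`).
#'   The default 0 trains with the pure soft Dice loss.
#' @param max_restarts multi-start collapse recovery: at the end of training
#'   the labels' classes are compared with the classes the model actually
#'   predicts on (a sample of) the training images; if any labeled class is
#'   entirely absent from the predictions -- the vanishing-gradient failure
#'   mode of softmax Dice, an initialization lottery from which training
#'   cannot recover -- optimization restarts from a fresh seed-derived
#'   initialization, up to `max_restarts` times (the same multi-start idea
#'   as `kmeans(nstart = )`). Deterministic for a fixed seed; 0 disables.
#' @return A `train_config` list.
#' @export
train_config <- function(arch = c("unetpp", "unet", "vnet2d"),
                         profile = c("desk", "paper"),
                         n_classes = nrow(schema),
                         schema = default_schema(),
                         learning_rate = NULL, weight_decay = 1e-5,
                         batch_size = NULL, epochs = NULL, seed = 42L,
                         input_shape = NULL, depth = NULL, channels = NULL,
                         deep_supervision = TRUE, flip_prob = 0.5,
                         include_background = TRUE, ce_weight = 0,
                         max_restarts = 2L) {
  arch <- match.arg(arch)
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (is.null(learning_rate)) learning_rate <- 3e-3
    if (is.null(batch_size)) batch_size <- 2L
    if (is.null(epochs)) epochs <- 50L
    if (is.null(input_shape)) input_shape <- c(128L, 64L)
    if (is.null(depth)) depth <- if (arch == "unetpp") 3L else 2L
    if (is.null(channels)) channels <- if (arch == "unetpp") c(16L, 16L, 32L) else c(16L, 16L)
  } else {
    if (is.null(learning_rate)) learning_rate <- 8e-5
    if (is.null(batch_size)) batch_size <- 8L
    if (is.null(epochs)) epochs <- 3000L
    if (is.null(input_shape)) input_shape <- c(512L, 1024L)
    if (is.null(depth)) depth <- 4L
    if (is.null(channels)) channels <- c(32L, 64L, 128L, 256L)
  }
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(channels) != depth) stop("channels must have one width per level")
  if (any(input_shape %% 2^(depth - 1) != 0))
    stop("input_shape must be divisible by 2^(depth-1)")
  if (ce_weight < 0) stop("ce_weight must be >= 0")
  structure(list(arch = arch, profile = profile, n_classes = as.integer(n_classes),
                 schema = schema, learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 input_shape = as.integer(input_shape), depth = as.integer(depth),
                 channels = as.integer(channels),
                 deep_supervision = isTRUE(deep_supervision) && arch == "unetpp",
                 flip_prob = flip_prob,
                 include_background = include_background,
                 ce_weight = ce_weight,
                 max_restarts = as.integer(max_restarts)),
            class = "train_config")
}

#' Build an untrained segmentation network
#'
#' Parameter initialization is He-normal, seeded from `cfg$seed`, so two
#' builds with the same config are identical. The model maps a (rows, cols)
#' intensity grid to `n_classes` score maps of the same spatial shape.
#'
#' @param cfg a [train_config()].
#' @return A `limbseg_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  params <- with_seed(cfg$seed, init_params(cfg))
  structure(list(arch = cfg$arch, n_classes = cfg$n_classes, cfg = cfg,
                 params = params, trained = FALSE),
            class = "limbseg_model")
}

init_params <- function(cfg) {
  ch <- cfg$channels; L <- cfg$depth; nc <- cfg$n_classes
  p <- list()
  add <- function(x) p <<- c(p, x)
  # every 3x3 conv is followed by instance normalization (conv-IN-ReLU
  # blocks, the convention of standard U-Net-family implementations)
  add_cn <- function(Cin, Cout, prefix) {
    add(p_conv3(Cin, Cout, prefix)); add(p_norm(Cout, prefix))
  }
  if (cfg$arch == "unet") {
    cin <- 1L
    for (l in seq_len(L)) {
      add_cn(cin, ch[l], sprintf("enc%d.c1", l))
      add_cn(ch[l], ch[l], sprintf("enc%d.c2", l))
      cin <- ch[l]
    }
    for (l in rev(seq_len(L - 1))) {
      add_cn(ch[l + 1], ch[l], sprintf("up%d", l))
      add_cn(2L * ch[l], ch[l], sprintf("dec%d.c1", l))
      add_cn(ch[l], ch[l], sprintf("dec%d.c2", l))
    }
    add(p_conv1(ch[1], nc, "head", zero = TRUE))
  } else if (cfg$arch == "vnet2d") {
    cin <- 1L
    for (l in seq_len(L)) {
      add_cn(cin, ch[l], sprintf("enc%d.c1", l))
      add_cn(ch[l], ch[l], sprintf("enc%d.c2", l))
      if (cin != ch[l]) add(p_conv1(cin, ch[l], sprintf("enc%d.proj", l)))
      if (l < L) add_cn(ch[l], ch[l + 1], sprintf("down%d", l))  # strided
      cin <- ch[l + 1]
    }
    for (l in rev(seq_len(L - 1))) {
      add_cn(ch[l + 1], ch[l], sprintf("up%d", l))
      add_cn(2L * ch[l], ch[l], sprintf("dec%d.c1", l))
      add_cn(ch[l], ch[l], sprintf("dec%d.c2", l))
      add(p_conv1(2L * ch[l], ch[l], sprintf("dec%d.proj", l)))
    }
    add(p_conv1(ch[1], nc, "head", zero = TRUE))
  } else { # unetpp: node X[i][j], channels ch[i+1]
    for (i in 0:(L - 1)) {
      cin <- if (i == 0) 1L else ch[i]
      add_cn(cin, ch[i + 1], sprintf("x%d0.c1", i))
      add_cn(ch[i + 1], ch[i + 1], sprintf("x%d0.c2", i))
    }
    for (j in 1:(L - 1)) for (i in 0:(L - 1 - j)) {
      add_cn(ch[i + 2], ch[i + 1], sprintf("up%d%d", i, j))
      cin <- (j + 1L) * ch[i + 1]  # j same-level inputs + upsampled
      add_cn(cin, ch[i + 1], sprintf("x%d%d.c1", i, j))
      add_cn(ch[i + 1], ch[i + 1], sprintf("x%d%d.c2", i, j))
    }
    for (j in 1:(L - 1)) add(p_conv1(ch[1], nc, sprintf("head%d", j), zero = TRUE))
  }
  p
}

# forward pass; returns list of head score nodes (full resolution).
# pn: named list of param nodes; geoms indexed by level.
model_forward <- function(arch, cfg, pn, x, geoms) {
  L <- cfg$depth
  cn <- function(x, prefix, g) {  # conv3 + instance norm
    h <- ag_conv3(x, pn[[paste0(prefix, ".W")]], pn[[paste0(prefix, ".b")]], g)
    ag_instnorm(h, pn[[paste0(prefix, ".g")]], pn[[paste0(prefix, ".s")]])
  }
  cblock <- function(x, prefix, g) {
    h <- ag_relu(cn(x, paste0(prefix, ".c1"), g))
    ag_relu(cn(h, paste0(prefix, ".c2"), g))
  }
  rblock <- function(x, prefix, g) {  # residual: relu(IN(conv(relu(IN(conv)))) + proj(x))
    h <- ag_relu(cn(x, paste0(prefix, ".c1"), g))
    h <- cn(h, paste0(prefix, ".c2"), g)
    sk <- if (!is.null(pn[[paste0(prefix, ".proj.W")]]))
      ag_conv1(x, pn[[paste0(prefix, ".proj.W")]], pn[[paste0(prefix, ".proj.b")]]) else x
    ag_relu(ag_add(h, sk))
  }
  if (arch == "unet") {
    skips <- vector("list", L)
    h <- x
    for (l in seq_len(L)) {
      if (l > 1) h <- ag_maxpool(h, geoms[[l - 1]])
      h <- cblock(h, sprintf("enc%d", l), geoms[[l]])
      skips[[l]] <- h
    }
    for (l in rev(seq_len(L - 1))) {
      h <- ag_upsample2(h, geoms[[l + 1]])
      h <- ag_relu(cn(h, sprintf("up%d", l), geoms[[l]]))
      h <- ag_concat(skips[[l]], h)
      h <- cblock(h, sprintf("dec%d", l), geoms[[l]])
    }
    list(ag_conv1(h, pn[["head.W"]], pn[["head.b"]]))
  } else if (arch == "vnet2d") {
    skips <- vector("list", L)
    h <- x
    for (l in seq_len(L)) {
      h <- rblock(h, sprintf("enc%d", l), geoms[[l]])
      skips[[l]] <- h
      if (l < L) {
        h <- cn(h, sprintf("down%d", l), geoms[[l]])
        h <- ag_relu(ag_subsample2(h, geoms[[l]]))
      }
    }
    for (l in rev(seq_len(L - 1))) {
      h <- ag_upsample2(h, geoms[[l + 1]])
      h <- ag_relu(cn(h, sprintf("up%d", l), geoms[[l]]))
      h <- ag_concat(skips[[l]], h)
      h <- rblock(h, sprintf("dec%d", l), geoms[[l]])
    }
    list(ag_conv1(h, pn[["head.W"]], pn[["head.b"]]))
  } else { # unetpp
    X <- vector("list", L)
    for (i in 0:(L - 1)) {
      inp <- if (i == 0) x else ag_maxpool(X[[i]][[1]], geoms[[i]])
      X[[i + 1]] <- list(cblock(inp, sprintf("x%d0", i), geoms[[i + 1]]))
    }
    for (j in 1:(L - 1)) for (i in 0:(L - 1 - j)) {
      up <- ag_upsample2(X[[i + 2]][[j]], geoms[[i + 2]])
      up <- ag_relu(cn(up, sprintf("up%d%d", i, j), geoms[[i + 1]]))
      h <- X[[i + 1]][[1]]
      if (j > 1) for (jj in 2:j) h <- ag_concat(h, X[[i + 1]][[jj]])
      h <- ag_concat(h, up)
      X[[i + 1]][[j + 1]] <- cblock(h, sprintf("x%d%d", i, j), geoms[[i + 1]])
    }
    heads <- lapply(1:(L - 1), function(j)
      ag_conv1(X[[1]][[j + 1]], pn[[sprintf("head%d.W", j)]], pn[[sprintf("head%d.b", j)]]))
    if (isTRUE(cfg$deep_supervision)) heads else heads[length(heads)]
  }
}

level_geoms <- function(H, W, L) {
  lapply(seq_len(L), function(l) get_geom(H %/% 2^(l - 1), W %/% 2^(l - 1)))
}

param_nodes <- function(params) lapply(params, ag_node)

#' Soft Dice loss between class probabilities and a label map
#'
#' `1 - mean_c [ 2 sum(p_c g_c) / (sum p_c + sum g_c) ]` over the evaluated
#' classes, in `[0, 1]`; exactly 0 when the prediction is the one-hot ground
#' truth (a class empty in both contributes a Dice of 1 via the epsilon
#' guard).
#'
#' @param pred_probs per-class probabilities: an H x W x C array or an
#'   (H*W) x C matrix, rows summing to 1.
#' @param label a [labelmap()] whose codes index the schema rows / channels.
#' @param schema [label_schema()] giving the channel order; defaults to the
#'   label's schema.
#' @param include_background include channel 1 (background) in the mean.
#' @return Scalar loss.
#' @export
dice_loss <- function(pred_probs, label, schema = label$schema,
                      include_background = TRUE) {
  stopifnot(inherits(label, "limb_labelmap"))
  C <- nrow(schema)
  if (length(dim(pred_probs)) == 3) {
    if (!all(dim(pred_probs)[1:2] == dim(label$codes)))
      stop("prediction and label shapes differ")
    P <- matrix(pred_probs, ncol = C)
  } else {
    P <- as.matrix(pred_probs)
    if (nrow(P) != length(label$codes) || ncol(P) != C)
      stop("prediction and label shapes differ")
  }
  G <- onehot_codes(label$codes, schema)
  idx <- if (include_background) seq_len(C) else which(schema$code != 0L)
  1 - mean(soft_dice_terms(P, G, idx))
}

onehot_codes <- function(codes, schema) {
  ch <- match(as.vector(codes), schema$code)
  G <- matrix(0, length(codes), nrow(schema))
  G[cbind(seq_along(ch), ch)] <- 1
  G
}

#' Train a segmentation network
#'
#' Runs seeded AdamW optimization of the soft Dice loss over the dataset.
#' Images must already be preprocessed to the configured input shape (use
#' [prepare_sample()]); horizontal-flip augmentation is applied on the fly
#' with probability `cfg$flip_prob`. Everything -- initialization, shuffling,
#' flips -- flows from `cfg$seed`, so a rerun reproduces the fit exactly on
#' one device.
#'
#' @param model a [build_model()] output (or NULL to build from `cfg`).
#' @param dataset non-empty list of samples, each with `$image`
#'   ([image2d()]) and `$mask` ([labelmap()]) on the configured grid.
#' @param cfg the [train_config()].
#' @return A `limbseg_fit`: the trained `model`, `history` (per-epoch mean
#'   loss, length `cfg$epochs`), and `cfg`.
#' @seealso [predict.limbseg_fit()], [plot.limbseg_fit()]
#' @export
train_model <- function(model = NULL, dataset, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) == 0) stop("dataset must be non-empty")
  if (is.null(model)) model <- build_model(cfg)
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  for (s in dataset)
    if (!all(dim(s$image$values) == c(H, W)))
      stop("all images must be preprocessed to the configured input shape (",
           H, " x ", W, ")")
  Xs <- lapply(dataset, function(s) matrix(as.vector(s$image$values), ncol = 1))
  Gs <- lapply(dataset, function(s) onehot_codes(s$mask$codes, cfg$schema))
  flip_idx <- as.vector(matrix(seq_len(H * W), H, W)[, W:1])
  geoms <- level_geoms(H, W, cfg$depth)
  class_idx <- if (cfg$include_background) seq_len(cfg$n_classes) else
    which(cfg$schema$code != 0L)
  n <- length(dataset)
  labeled_codes <- sort(unique(unlist(lapply(dataset, function(s)
    unique(as.vector(s$mask$codes))))))
  probe_idx <- seq_len(min(4L, n))
  attempt <- 0L
  repeat {
    params <- if (attempt == 0L) model$params else
      with_seed(cfg$seed + 1009L * attempt, init_params(cfg))
    state <- adamw_state(params)
    history <- numeric(cfg$epochs)
    collapsed <- FALSE
    with_seed(cfg$seed + attempt, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        ep_losses <- c()
        for (start in seq(1, n, by = cfg$batch_size)) {
          batch <- ord[start:min(start + cfg$batch_size - 1, n)]
          grads <- NULL
          batch_loss <- 0
          for (s_i in batch) {
            X <- Xs[[s_i]]; G <- Gs[[s_i]]
            if (cfg$flip_prob > 0 && runif(1) < cfg$flip_prob) {
              X <- X[flip_idx, , drop = FALSE]; G <- G[flip_idx, , drop = FALSE]
            }
            pn <- param_nodes(params)
            heads <- model_forward(cfg$arch, cfg, pn, ag_node(X), geoms)
            losses <- lapply(heads, function(hd) {
              l <- ag_dice_loss(hd, G = G, class_idx = class_idx)
              if (cfg$ce_weight > 0)
                l <- ag_add(l, ag_scale(ag_ce_loss(hd, G), cfg$ce_weight))
              l
            })
            total <- Reduce(ag_add, losses)
            ag_backward(total, seed_grad = 1 / length(losses))
            batch_loss <- batch_loss + total$val / length(losses)
            g <- lapply(pn, function(p) p$grad)
            grads <- if (is.null(grads)) g else
              Map(function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b,
                  grads, g)
          }
          nb <- length(batch)
          grads <- lapply(grads, function(g) if (is.null(g)) NULL else g / nb)
          upd <- adamw_step(params, grads, state, cfg$learning_rate, cfg$weight_decay)
          params <- upd$params; state <- upd$state
          ep_losses <- c(ep_losses, batch_loss / nb)
        }
        history[ep] <- mean(ep_losses)
        if (ep == cfg$epochs && attempt < cfg$max_restarts) {
          seen <- predicted_codes(params, cfg, Xs[probe_idx], geoms)
          if (length(setdiff(labeled_codes, seen))) {
            collapsed <- TRUE
            break
          }
        }
      }
    })
    if (!collapsed) break
    attempt <- attempt + 1L
  }
  model$params <- params
  model$trained <- TRUE
  structure(list(model = model, history = history, cfg = cfg,
                 final_loss = history[cfg$epochs], restarts = attempt),
            class = "limbseg_fit")
}

# union of class codes the current parameters predict on a set of inputs
predicted_codes <- function(params, cfg, X_list, geoms) {
  pn <- param_nodes(params)
  seen <- integer(0)
  for (X in X_list) {
    heads <- model_forward(cfg$arch, cfg, pn, ag_node(X), geoms)
    S <- heads[[length(heads)]]$val
    seen <- union(seen, cfg$schema$code[unique(max.col(S, ties.method = "first"))])
  }
  sort(seen)
}

#' Segment an image with a model
#'
#' Forward pass plus per-pixel argmax over class scores; for a
#' deep-supervision U-Net++ the last (full-depth) head is used. The output
#' label map carries the input image's spacing and the training schema.
#'
#' @param model a `limbseg_model` or `limbseg_fit`.
#' @param img a [image2d()] preprocessed as in training; its (rows, cols)
#'   must be divisible by `2^(depth-1)`.
#' @return A [labelmap()].
#' @export
segment_image <- function(model, img) {
  if (inherits(model, "limbseg_fit")) model <- model$model
  stopifnot(inherits(model, "limbseg_model"), inherits(img, "limb_image"))
  cfg <- model$cfg
  H <- nrow(img$values); W <- ncol(img$values)
  if (any(c(H, W) %% 2^(cfg$depth - 1) != 0))
    stop("image shape incompatible with model depth")
  geoms <- level_geoms(H, W, cfg$depth)
  pn <- param_nodes(model$params)
  heads <- model_forward(cfg$arch, cfg, pn, ag_node(matrix(as.vector(img$values), ncol = 1)), geoms)
  S <- heads[[length(heads)]]$val
  codes <- matrix(cfg$schema$code[max.col(S, ties.method = "first")], H, W)
  labelmap(codes, img$spacing, cfg$schema)
}

#' Class-probability maps for an image
#'
#' @inheritParams segment_image
#' @return An H x W x n_classes array of softmax probabilities.
#' @export
predict_probs <- function(model, img) {
  if (inherits(model, "limbseg_fit")) model <- model$model
  cfg <- model$cfg
  H <- nrow(img$values); W <- ncol(img$values)
  geoms <- level_geoms(H, W, cfg$depth)
  pn <- param_nodes(model$params)
  heads <- model_forward(cfg$arch, cfg, pn, ag_node(matrix(as.vector(img$values), ncol = 1)), geoms)
  array(softmax_rows(heads[[length(heads)]]$val), dim = c(H, W, cfg$n_classes))
}

#' @export
predict.limbseg_model <- function(object, newdata, ...) segment_image(object, newdata)

#' Predict method for fitted segmentation models
#'
#' @param object a `limbseg_fit`.
#' @param newdata a [image2d()] or list of them.
#' @param ... unused.
#' @return A [labelmap()] (or list of them).
#' @export
predict.limbseg_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "limb_image")) return(segment_image(object, newdata))
  lapply(newdata, segment_image, model = object)
}

#' @export
print.limbseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<limbseg_model> %s, %d classes, depth %d, channels (%s), %s, %d parameters\n",
              x$arch, x$n_classes, x$cfg$depth,
              paste(x$cfg$channels, collapse = ", "),
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

#' @export
print.limbseg_fit <- function(x, ...) {
  cat(sprintf("<limbseg_fit> %s (%s profile), %d epochs, final Dice loss %.4f\n",
              x$cfg$arch, x$cfg$profile, x$cfg$epochs, x$final_loss))
  invisible(x)
}

#' @export
summary.limbseg_fit <- function(object, ...) {
  h <- object$history
  dec <- max(1L, length(h) %/% 10L)
  cat(sprintf("%s fit, %d epochs, lr %g, batch %d\n", object$cfg$arch,
              object$cfg$epochs, object$cfg$learning_rate, object$cfg$batch_size))
  cat(sprintf("Dice loss: first-decile median %.4f -> last-decile median %.4f (final %.4f)\n",
              median(head(h, dec)), median(tail(h, dec)), object$final_loss))
  invisible(object)
}

#' Plot the training loss history
#'
#' @param x a `limbseg_fit`.
#' @param ... passed to [plot()].
#' @export
plot.limbseg_fit <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l", xlab = "epoch",
       ylab = "mean Dice loss", main = paste(x$cfg$arch, "training"), ...)
  invisible(x)
}

#' Prepare a phantom or image/mask pair for training
#'
#' Runs the deterministic preprocessing pipeline and resizes the pair to the
#' configured input shape.
#'
#' @param sample list with `$image` and `$mask` (a `phantom_sample` works).
#' @param cfg a [train_config()].
#' @param pre a [preprocess_config()]; its resize shape is overridden by
#'   `cfg$input_shape`.
#' @return List with preprocessed `image` and `mask`.
#' @export
prepare_sample <- function(sample, cfg, pre = preprocess_config()) {
  img <- preprocess_pipeline(sample$image, pre)
  resize_pair(img, sample$mask, cfg$input_shape)
}
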