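# Minimal neural-network engine for 2D dense prediction, written directly on
# BLAS matrix products. A feature map on an H x W grid is a (H*W) x C matrix
# in R's column-major pixel order; a 3x3 convolution is the sum over the nine
# kernel offsets of a row-shifted copy of the input times the corresponding
# Cin x Cout weight slice ("shift-and-add"), so forward and backward passes
# are plain matmuls. A tiny tape autograd (environments as nodes) links the
# ops; AdamW does the updates. Everything is seeded and single-threaded
# deterministic.

# ---- grid geometry (shift / pool / upsample index vectors), cached per H x W

.geom_cache <- new.env(parent = emptyenv())

# offsets ordered di fastest: k -> (di, dj); negation maps k -> 10 - k
.offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))

get_geom <- function(H, W) {
  key <- paste0(H, "x", W)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  HW <- H * W
  r <- rep.int(seq_len(H), W)
  c_ <- rep(seq_len(W), each = H)
  shift <- lapply(seq_len(9), function(k) {
    di <- .offs[k, 1]; dj <- .offs[k, 2]
    rs <- r + di; cs <- c_ + dj
    ok <- rs >= 1 & rs <= H & cs >= 1 & cs <= W
    idx <- rep.int(HW + 1L, HW)
    idx[ok] <- rs[ok] + (cs[ok] - 1L) * H
    idx
  })
  g <- list(H = H, W = W, HW = HW, shift = shift)
  if (H %% 2 == 0 && W %% 2 == 0) {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    r2 <- rep.int(seq_len(H2), W2); c2 <- rep(seq_len(W2), each = H2)
    g$pool <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o)
      (2L * r2 - 1L + o[1]) + (2L * c2 - 2L + o[2]) * H)
    g$sub <- g$pool[[1]]                       # stride-2 sampling points
    ru <- rep.int(seq_len(2L * H), 2L * W); cu <- rep(seq_len(2L * W), each = 2L * H)
    g$up <- ((ru + 1L) %/% 2L) + (((cu + 1L) %/% 2L) - 1L) * H
  }
  .geom_cache[[key]] <- g
  g
}

# ---- autograd tape -----------------------------------------------------------

ag_node <- function(val, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val; e$parents <- parents; e$backfn <- backfn; e$grad <- NULL
  e
}

ag_backward <- function(root, seed_grad = 1) {
  order <- list(); n <- 0L
  visit <- function(node) {
    if (isTRUE(node$.seen)) return()
    node$.seen <- TRUE
    for (p in node$parents) visit(p)
    n <<- n + 1L
    order[[n]] <<- node
  }
  visit(root)
  root$grad <- seed_grad
  for (i in rev(seq_len(n))) {
    node <- order[[i]]
    node$.seen <- NULL
    if (is.null(node$backfn) || is.null(node$grad)) next
    pg <- node$backfn(node$grad)
    for (j in seq_along(pg)) {
      if (is.null(pg[[j]])) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
  }
  invisible(root)
}

# ---- ops ---------------------------------------------------------------------

ag_conv3 <- function(x, w, b, g) {
  X <- x$val; W <- w$val; Cin <- ncol(X); HW <- nrow(X)
  Xp <- rbind(X, 0)
  Y <- matrix(b$val, HW, length(b$val), byrow = TRUE)
  for (k in 1:9) {
    rows <- ((k - 1L) * Cin + 1L):(k * Cin)
    Y <- Y + Xp[g$shift[[k]], , drop = FALSE] %*% W[rows, , drop = FALSE]
  }
  ag_node(Y, list(x, w, b), function(dY) {
    dW <- W; dW[] <- 0
    dX <- matrix(0, HW, Cin)
    for (k in 1:9) {
      rows <- ((k - 1L) * Cin + 1L):(k * Cin)
      dW[rows, ] <- crossprod(Xp[g$shift[[k]], , drop = FALSE], dY)
      Tp <- rbind(dY %*% t(W[rows, , drop = FALSE]), 0)
      dX <- dX + Tp[g$shift[[10L - k]], , drop = FALSE]
    }
    list(dX, dW, colSums(dY))
  })
}

ag_conv1 <- function(x, w, b) {
  X <- x$val; W <- w$val
  Y <- X %*% W + matrix(b$val, nrow(X), length(b$val), byrow = TRUE)
  ag_node(Y, list(x, w, b), function(dY)
    list(dY %*% t(W), crossprod(X, dY), colSums(dY)))
}

ag_relu <- function(x) {
  mask <- x$val > 0
  ag_node(x$val * mask, list(x), function(dY) list(dY * mask))
}

ag_maxpool <- function(x, g) {
  X <- x$val; C <- ncol(X)
  M <- X[g$pool[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(M), C)
  for (k in 2:4) {
    Xi <- X[g$pool[[k]], , drop = FALSE]
    upd <- Xi > M
    M[upd] <- Xi[upd]; arg[upd] <- k
  }
  ag_node(M, list(x), function(dY) {
    dX <- matrix(0, nrow(X), C)
    for (k in 1:4) dX[g$pool[[k]], ] <- dY * (arg == k)
    list(dX)
  })
}

ag_subsample2 <- function(x, g) {
  idx <- g$sub
  ag_node(x$val[idx, , drop = FALSE], list(x), function(dY) {
    dX <- matrix(0, g$HW, ncol(dY))
    dX[idx, ] <- dY
    list(dX)
  })
}

ag_upsample2 <- function(x, g) {
  # g is the geometry of the *input* grid; output is 2H x 2W
  idx <- g$up
  ag_node(x$val[idx, , drop = FALSE], list(x), function(dY)
    list(unname(rowsum(dY, idx, reorder = TRUE))))
}

# instance normalization: per-channel standardization over the spatial grid
# of one image, with learned scale and shift
ag_instnorm <- function(x, g, b, eps = 1e-5) {
  X <- x$val
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  v <- colMeans(Xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- sweep(Xc, 2, inv_sd, "*")
  Y <- sweep(sweep(Xhat, 2, g$val, "*"), 2, b$val, "+")
  ag_node(Y, list(x, g, b), function(dY) {
    dXhat <- sweep(dY, 2, g$val, "*")
    m1 <- colMeans(dXhat)
    m2 <- colMeans(dXhat * Xhat)
    dX <- sweep(sweep(dXhat, 2, m1) - sweep(Xhat, 2, m2, "*"), 2, inv_sd, "*")
    list(dX, colSums(dY * Xhat), colSums(dY))
  })
}

ag_concat <- function(a, b) {
  na <- ncol(a$val)
  ag_node(cbind(a$val, b$val), list(a, b), function(dY)
    list(dY[, seq_len(na), drop = FALSE], dY[, -seq_len(na), drop = FALSE]))
}

ag_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(dY) list(dY, dY))
}

# ---- soft Dice loss on softmax scores ---------------------------------------

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

soft_dice_terms <- function(P, G, class_idx, eps = 1e-7) {
  I <- colSums(P[, class_idx, drop = FALSE] * G[, class_idx, drop = FALSE])
  A <- colSums(P[, class_idx, drop = FALSE]) + colSums(G[, class_idx, drop = FALSE])
  (2 * I + eps) / (A + eps)
}

# loss node: 1 - mean_c softDice_c on softmax(S), gradient flows into scores
ag_dice_loss <- function(scores, G, class_idx, eps = 1e-7) {
  S <- scores$val
  P <- softmax_rows(S)
  Pc <- P[, class_idx, drop = FALSE]; Gc <- G[, class_idx, drop = FALSE]
  I <- colSums(Pc * Gc)
  A <- colSums(Pc) + colSums(Gc)
  D <- (2 * I + eps) / (A + eps)
  loss <- 1 - mean(D)
  K <- length(class_idx)
  ag_node(loss, list(scores), function(dL) {
    dP <- matrix(0, nrow(S), ncol(S))
    dP[, class_idx] <- -(dL / K) *
      sweep(sweep(2 * Gc, 2, D, "-"), 2, A + eps, "/")
    dS <- P * (dP - rowSums(dP * P))
    list(dS)
  })
}

# cross-entropy on softmax scores: -mean_i log p(true class). Its logit
# gradient (P - G)/n does not vanish for a suppressed class, which is what
# makes a small CE term an effective reviver against softmax-Dice class
# collapse.
ag_ce_loss <- function(scores, G) {
  S <- scores$val
  P <- softmax_rows(S)
  n <- nrow(S)
  loss <- -sum(G * log(pmax(P, 1e-12))) / n
  ag_node(loss, list(scores), function(dL) list(dL * (P - G) / n))
}

ag_scale <- function(x, k) {
  ag_node(k * x$val, list(x), function(dY) list(k * dY))
}

# ---- parameters and AdamW ----------------------------------------------------

p_conv3 <- function(Cin, Cout, prefix) {
  W <- matrix(rnorm(9 * Cin * Cout, 0, sqrt(2 / (9 * Cin))), 9 * Cin, Cout)
  stats::setNames(list(W, numeric(Cout)), paste0(prefix, c(".W", ".b")))
}

# conv + instance norm parameter pair
p_norm <- function(C, prefix) {
  stats::setNames(list(rep(1, C), numeric(C)), paste0(prefix, c(".g", ".s")))
}

p_conv1 <- function(Cin, Cout, prefix, zero = FALSE) {
  W <- if (zero) matrix(0, Cin, Cout) else
    matrix(rnorm(Cin * Cout, 0, sqrt(2 / Cin)), Cin, Cout)
  stats::setNames(list(W, numeric(Cout)), paste0(prefix, c(".W", ".b")))
}

adamw_state <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] - lr *
      ((state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
         weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
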