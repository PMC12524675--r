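# Brute-force oracles: explicit pixel-set loops, independent of the package's
# distance-transform implementation. Deliberately slow and literal.

oracle_class_metrics <- function(pred_codes, label_codes, cd) {
  P <- which(pred_codes == cd, arr.ind = TRUE)
  L <- which(label_codes == cd, arr.ind = TRUE)
  np <- nrow(P); nl <- nrow(L)
  inter <- sum(pred_codes == cd & label_codes == cd)
  union <- sum(pred_codes == cd | label_codes == cd)
  iou <- if (union == 0) 1 else inter / union
  dc <- if (np + nl == 0) 1 else 2 * inter / (np + nl)
  if (np == 0 && nl == 0) {
    ad <- 0; hd <- 0
  } else if (np == 0 || nl == 0) {
    ad <- Inf; hd <- Inf
  } else {
    # all pairwise Euclidean distances
    D <- sqrt(outer(P[, 1], L[, 1], "-")^2 + outer(P[, 2], L[, 2], "-")^2)
    d_pl <- apply(D, 1, min)   # each pred pixel to nearest label pixel
    d_lp <- apply(D, 2, min)   # each label pixel to nearest pred pixel
    ad <- (mean(d_pl) + mean(d_lp)) / 2
    hd <- max(max(d_pl), max(d_lp))
  }
  raad <- if (nl > 0) abs(np - nl) / nl * 100 else if (np == 0) 0 else 100
  c(iou = iou, dice = dc, ad = ad, hd = hd, raad = raad,
    pred_area = np, label_area = nl)
}

oracle_metrics <- function(pred_codes, label_codes, classes) {
  per <- t(vapply(classes, function(cd)
    oracle_class_metrics(pred_codes, label_codes, cd), numeric(7)))
  la <- per[, "label_area"]
  w <- if (sum(la) > 0) la / sum(la) else rep(0, length(la))
  list(per = per, mean_iou = mean(per[, "iou"]), mean_dice = mean(per[, "dice"]),
       mean_ad = mean(per[, "ad"]), mean_hd = mean(per[, "hd"]),
       weighted_raad = sum(per[, "raad"] * w))
}

# random multiclass label matrix
random_codes <- function(nr, nc, n_classes) {
  matrix(sample.int(n_classes, nr * nc, replace = TRUE) - 1L, nr, nc)
}

# schema whose codes are 0..k with all non-background classes "muscle-free"
plain_schema <- function(k) {
  label_schema(c("background", paste0("c", seq_len(k))), 0:k,
               c(FALSE, rep(TRUE, k)))
}
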