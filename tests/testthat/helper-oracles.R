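# Independent oracles used to cross-check the package implementations.

# Brute-force per-pixel confusion tally.
confusion_loop <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Direct formula evaluation of the six metrics from counts.
metrics_loop <- function(cc) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- rate(cc$tp, cc$tp + cc$fp)
  sens <- rate(cc$tp, cc$tp + cc$fn)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(iou = rate(cc$tp, cc$tp + cc$fp + cc$fn),
       accuracy = rate(cc$tp + cc$tn, cc$tp + cc$tn + cc$fp + cc$fn),
       specificity = rate(cc$tn, cc$tn + cc$fp),
       sensitivity = sens, precision = prec, f1 = f1)
}

# Dice coefficient; related to the Jaccard index by J = D / (2 - D).
dice_coef <- function(p, g) {
  s <- sum(p) + sum(g)
  if (s == 0) return(NA_real_)
  2 * sum(p * g) / s
}

# Closed-form parameter count of the U-Net architecture, summed layer by
# layer: 3x3 convs contribute 9*cin*cout + cout, the 2x2 upsampling kernels
# 4*cin*cout + cout, the final 1x1 conv cin*ncl + ncl.
unet_param_count_oracle <- function(depth, base, in_ch = 1, ncl = 2) {
  ch <- function(s) base * 2^(s - 1)
  total <- 0
  for (s in seq_len(depth)) {
    cin <- if (s == 1) in_ch else ch(s - 1)
    total <- total + 9 * cin * ch(s) + ch(s) + 9 * ch(s) * ch(s) + ch(s)
  }
  cb <- ch(depth + 1)
  total <- total + 9 * ch(depth) * cb + cb + 9 * cb * cb + cb
  for (s in seq_len(depth)) {
    clow <- if (s == depth) cb else ch(s + 1)
    total <- total + 4 * clow * ch(s) + ch(s) +
      9 * 2 * ch(s) * ch(s) + ch(s) + 9 * ch(s) * ch(s) + ch(s)
  }
  total + in_ch * 0 + ch(1) * ncl + ncl
}

# Random binary mask / probability map pair of a given size.
random_mask <- function(n, p = 0.3) matrix(rbinom(n * n, 1, p), n, n)
random_probs <- function(n) matrix(runif(n * n), n, n)

# Binary disk image centered in an n x n frame.
disk_mask <- function(n, radius = n / 4, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  (d2 <= radius^2) * 1
}

# A tiny standardized disk-segmentation sample set for fast training tests.
disk_dataset <- function(n_img = 6, size = 32, seed = 1) {
  set.seed(seed)
  samples <- lapply(seq_len(n_img), function(i) {
    r <- runif(1, size / 6, size / 3.5)
    cx <- runif(1, size * 0.35, size * 0.65)
    cy <- runif(1, size * 0.35, size * 0.65)
    m <- disk_mask(size, r, cx, cy)
    img <- m * 2 + 1 + matrix(rnorm(size^2, 0, 0.05), size, size)
    st <- dataset_statistics(img)
    list(image = standardize(img, st$mean, st$std), mask = m)
  })
  samples
}
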