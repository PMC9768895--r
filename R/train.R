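#' Training configuration
#'
#' Defaults follow the study protocol for clinical runs: Adam with learning
#' rate 1e-5, batch size 4, up to 2000 epochs, one network per (zone, plane)
#' pair. Desk-scale demo runs override `max_epochs` (<= 200) and use a
#' larger learning rate so the small phantom task converges within the
#' budget; see the methods vignette.
#'
#' @param learning_rate Adam step size (> 0); default 1e-5.
#' @param batch_size images per gradient step (>= 1); default 4.
#' @param max_epochs training budget; default 2000.
#' @param lambda_ce weight of the auxiliary cross-entropy term; default 0.
#' @param seed RNG seed for batching and augmentation.
#' @param zone_id,plane labels of the (zone, plane) pair this network serves.
#' @param augment logical; sample a random geometric augmentation for every
#'   training image each epoch.
#' @param early_stopping logical; stop when the validation IoU has not
#'   improved for `patience` epochs (off by default, matching a fixed
#'   training budget).
#' @param patience plateau length for early stopping.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 4L,
                         max_epochs = 2000L, lambda_ce = 0, seed = 1L,
                         zone_id = NA_character_, plane = NA_character_,
                         augment = FALSE, early_stopping = FALSE,
                         patience = 15L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (max_epochs < 0L) stop("`max_epochs` must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lambda_ce = lambda_ce, seed = as.integer(seed),
                 zone_id = zone_id, plane = plane,
                 augment = isTRUE(augment),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience)),
            class = "train_config")
}

# Adam optimizer state over a flat named parameter list.
adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, gflat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- gflat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# Mean binarized IoU of a network over a list of image/mask pairs.
# Empty-vs-empty slices count as IoU 1 (a correct empty prediction).
eval_iou <- function(net, images, masks, batch_size = 8L) {
  n <- length(images)
  ious <- numeric(n)
  losses <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    probs <- unet_forward(net, images[i:j])$probs
    for (k in i:j) {
      p_fg <- matrix(probs[, , 2, k - i + 1], dim(probs)[1], dim(probs)[2])
      pred <- (p_fg > 0.5) * 1
      g <- masks[[k]]
      cc <- confusion(pred, g)
      denom <- cc$tp + cc$fp + cc$fn
      ious[k] <- if (denom == 0) 1 else cc$tp / denom
      inter <- sum(p_fg * g)
      uni <- sum(p_fg) + sum(g) - inter
      losses[k] <- if (uni == 0) 0 else 1 - inter / uni
    }
    i <- j + 1L
  }
  list(iou = mean(ious), loss = mean(losses))
}

#' Train a U-Net on a slice dataset
#'
#' Mini-batch Adam on the soft-IoU objective. Every epoch records training
#' and validation loss and binarized IoU; the checkpoint with the best
#' validation IoU is returned alongside the final network. Fully seeded:
#' identical config + dataset reproduce identical histories. Training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param cfg a [train_config()].
#' @param dataset list with `train` and `val`, each a list of samples; every
#'   sample is a list with `image` (H x W matrix, standardized) and `mask`
#'   (binary H x W matrix).
#' @param net optionally a pre-built [build_unet()] network; by default a
#'   depth-2, 8-channel network seeded from the training config.
#' @param verbose print a one-line summary every `verbose` epochs (0 = quiet).
#' @return list with `net` (best-validation checkpoint), `final_net`,
#'   `history` (data frame: epoch, train_loss, train_iou, val_loss,
#'   val_iou), and `best_epoch`.
#' @export
train_unet <- function(cfg, dataset, net = NULL, verbose = 0L) {
  stopifnot(inherits(cfg, "train_config"))
  tr <- dataset$train; va <- dataset$val
  if (length(tr) == 0L) stop("training set is empty")
  if (is.null(net))
    net <- build_unet(unet_config(depth = 2L, base_channels = 8L,
                                  seed = cfg$seed))
  tr_img <- lapply(tr, `[[`, "image"); tr_msk <- lapply(tr, `[[`, "mask")
  va_img <- lapply(va, `[[`, "image"); va_msk <- lapply(va, `[[`, "mask")

  flat <- flatten_params(net$params)
  state <- adam_init(flat)
  hist <- vector("list", cfg$max_epochs)
  best <- list(iou = -Inf, flat = flat, epoch = 0L)
  n <- length(tr)

  if (cfg$max_epochs == 0L)
    return(list(net = net, final_net = net,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     train_iou = numeric(),
                                     val_loss = numeric(),
                                     val_iou = numeric()),
                best_epoch = 0L))

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- with_seed(cfg$seed + epoch, sample.int(n))
    ep_loss <- 0; nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      ids <- perm[i:j]
      imgs <- tr_img[ids]; msks <- tr_msk[ids]
      if (cfg$augment) {
        for (k in seq_along(ids)) {
          ap <- sample_augmentation(
            seed = cfg$seed * 10000L + epoch * 100L + ids[k])
          au <- augment(imgs[[k]], msks[[k]], ap)
          imgs[[k]] <- au$image; msks[[k]] <- au$mask
        }
      }
      lg <- unet_loss_and_grads(net, imgs,
                                msks, lambda_ce = cfg$lambda_ce)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch))
      upd <- adam_step(flat, flatten_params(lg$grads), state,
                       cfg$learning_rate)
      flat <- upd$flat; state <- upd$state
      net$params <- unflatten_params(net$params, flat)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      i <- j + 1L
    }
    tr_eval <- eval_iou(net, tr_img, tr_msk)
    va_eval <- if (length(va)) eval_iou(net, va_img, va_msk)
               else list(iou = NA_real_, loss = NA_real_)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                train_iou = tr_eval$iou,
                                val_loss = va_eval$loss,
                                val_iou = va_eval$iou)
    if (verbose > 0L && epoch %% verbose == 0L)
      message(sprintf(
        "epoch %4d | train loss %.4f IoU %.3f | val loss %s IoU %s",
        epoch, ep_loss / nb, tr_eval$iou,
        formatC(va_eval$loss, format = "f", digits = 4),
        formatC(va_eval$iou, format = "f", digits = 3)))
    score <- if (is.na(va_eval$iou)) tr_eval$iou else va_eval$iou
    if (score > best$iou) {
      best <- list(iou = score, flat = flat, epoch = epoch)
    }
    if (cfg$early_stopping && epoch - best$epoch >= cfg$patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  best_net <- net
  best_net$params <- unflatten_params(net$params, best$flat)
  list(net = best_net, final_net = net, history = history,
       best_epoch = best$epoch)
}

#' Classify the pathological state of a slice from its predicted mask
#'
#' A slice is called amyloid-positive when the segmented lesion exceeds
#' `min_pixels`; the two-class score pair is derived from the mean
#' foreground probability under the mask.
#'
#' @param probs `[H, W, 2]` probability map from [unet_predict()].
#' @param min_pixels minimum lesion size to call a slice positive.
#' @return list with `positive` (logical) and `scores` (two-class vector
#'   summing to 1).
#' @export
classify_slice <- function(probs, min_pixels = 1L) {
  p_fg <- probs[, , 2]
  pred <- p_fg > 0.5
  npos <- sum(pred)
  score_fg <- if (npos > 0) mean(p_fg[pred]) else max(p_fg)
  positive <- npos >= min_pixels
  list(positive = positive, scores = c(negative = 1 - score_fg,
                                       positive = score_fg))
}
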