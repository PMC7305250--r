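#' Learning-rate schedule: halve on a Dice plateau
#'
#' Pure function implementing the training schedule: starting from `lr0`,
#' the learning rate is multiplied by `factor` whenever the monitored Dice
#' metric has failed to improve for `patience` consecutive epochs (the
#' counter then resets, the best-so-far is kept).
#'
#' @param dice_history numeric vector of the monitored Dice metric, one
#'   value per completed epoch.
#' @param lr0 initial learning rate.
#' @param factor multiplicative reduction (default 0.5).
#' @param patience consecutive non-improving epochs before a reduction
#'   (default 3).
#' @return numeric vector: the learning rate in effect after each epoch.
#' @examples
#' lr_schedule(c(.5, .5, .5, .5))       # 1e-4 1e-4 1e-4 5e-5
#' lr_schedule(c(.5, .6, .7, .8))       # stays at 1e-4
#' @export
lr_schedule <- function(dice_history, lr0 = 1e-4, factor = 0.5, patience = 3) {
  lr <- lr0; best <- -Inf; bad <- 0L
  out <- numeric(length(dice_history))
  for (i in seq_along(dice_history)) {
    if (dice_history[i] > best) {
      best <- dice_history[i]; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) { lr <- lr * factor; bad <- 0L }
    }
    out[i] <- lr
  }
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),  # zero, same shape as the param
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# mean hard Dice over foreground classes present in the truth
hard_dice_labels <- function(pred, truth) {
  classes <- intersect(1:3, unique(as.integer(truth)))
  if (!length(classes)) return(NA_real_)
  mean(vapply(classes, function(c)
    dice_coefficient(which(pred == c), which(truth == c)), 0))
}

#' Train the dense U-net with Adam and Dice loss
#'
#' Per-patch stochastic optimization (Adam) of the soft Dice loss, with the
#' plateau learning-rate schedule of [lr_schedule()]: the monitored metric
#' is the mean hard Dice over foreground classes on the validation patches
#' (or, if none are given, on the training patches). Seeded runs are
#' reproducible.
#'
#' @param net an untrained (or previously trained) `dense_unet`.
#' @param patches list of 3D HU arrays, all the same shape.
#' @param truths list of 3D integer label arrays (0..3) aligned to `patches`.
#' @param val_patches,val_truths optional held-out pairs for the monitored
#'   Dice metric.
#' @param max_epochs number of epochs.
#' @param lr0,factor,patience schedule parameters (see [lr_schedule()]).
#' @param augment optional list `(translate_vox, rotate_deg)` enabling
#'   on-the-fly axial translation/rotation augmentation of each patch.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param log_path optional path; per-epoch log written as tab-separated
#'   text (epoch, loss, val_dice, lr).
#' @param verbose print per-epoch progress.
#' @return the trained `dense_unet` with a `history` data frame
#'   (epoch, loss, val_dice, lr).
#' @export
train_dense_unet <- function(net, patches, truths,
                             val_patches = NULL, val_truths = NULL,
                             max_epochs = 30, lr0 = 1e-4, factor = 0.5,
                             patience = 3, augment = NULL, seed = 1,
                             log_path = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "dense_unet"))
  if (!length(patches)) stop("train_dense_unet: empty training set")
  if (length(patches) != length(truths))
    stop("train_dense_unet: patches and truths differ in length")
  state <- adam_init(net$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice = numeric(), lr = numeric())
  dice_hist <- numeric()
  lr <- lr0
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(length(patches))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        img <- patches[[i]]; lab <- truths[[i]]
        if (!is.null(augment)) {
          aug <- augment_patch(img, lab,
                               translate_vox = augment$translate_vox %||% 8,
                               rotate_deg = augment$rotate_deg %||% 10,
                               seed = NULL)
          img <- aug$image; lab <- aug$mask
        }
        fw <- unet_forward(net, img, keep_cache = TRUE)
        losses[ii] <- dice_loss(fw$prob, lab)
        grads <- unet_backward(net, fw, lab)
        upd <- adam_step(net$params, grads, state, lr)
        net$params <- upd$params; state <- upd$state
      }
      vd <- monitor_dice(net, val_patches %||% patches, val_truths %||% truths)
      dice_hist <- c(dice_hist, vd)
      lr <- tail(lr_schedule(dice_hist, lr0, factor, patience), 1)
      history[epoch, ] <- list(epoch, mean(losses), vd, lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_dice %.4f  lr %.2e",
                        epoch, mean(losses), vd, lr))
    }
  })
  net$history <- history
  if (!is.null(log_path))
    write.table(history, log_path, sep = "\t", row.names = FALSE, quote = FALSE)
  net
}

monitor_dice <- function(net, patches, truths) {
  ds <- vapply(seq_along(patches), function(i) {
    fw <- unet_forward(net, patches[[i]])
    pred <- argmax_labels(fw$prob)
    hard_dice_labels(pred, truths[[i]])
  }, 0)
  mean(ds, na.rm = TRUE)
}

# deterministic argmax over class rows: lowest class index wins ties
argmax_labels <- function(prob) {
  best <- prob[1, ]
  lab <- rep(0L, ncol(prob))
  for (c in 2:nrow(prob)) {
    better <- prob[c, ] > best
    lab[better] <- c - 1L
    best[better] <- prob[c, better]
  }
  lab
}

#' Per-patch class probabilities (generic over network kinds)
#'
#' `predict_patch()` is the single entry point [predict_volume()] uses, so a
#' stub "oracle" network -- returning the one-hot ground truth for any patch
#' -- can stand in for the trained model when testing the deterministic half
#' of the pipeline.
#'
#' @param net a `dense_unet` or `oracle_net`.
#' @param patch 3D HU array.
#' @param z_offset 0-based slice offset of the patch within the volume.
#' @param ... unused.
#' @return `n_classes` x n_voxels probability matrix.
#' @export
predict_patch <- function(net, patch, z_offset = 0L, ...) UseMethod("predict_patch")

#' @export
predict_patch.dense_unet <- function(net, patch, z_offset = 0L, ...) {
  unet_forward(net, patch)$prob
}

#' @rdname predict_patch
#' @param truth_mask a [class_mask] with the ground-truth labels.
#' @export
oracle_net <- function(truth_mask) {
  stopifnot(inherits(truth_mask, "class_mask"))
  structure(list(truth = truth_mask), class = "oracle_net")
}

#' @export
predict_patch.oracle_net <- function(net, patch, z_offset = 0L, ...) {
  d <- dim(patch)
  td <- dim(net$truth$labels)
  zi <- (z_offset + 1):(z_offset + d[1])
  lab <- array(0L, dim = d)
  ok <- zi <= td[1]
  lab[ok, , ] <- net$truth$labels[zi[ok], , , drop = FALSE]
  P <- matrix(0, 4, length(lab))
  P[cbind(as.integer(lab) + 1L, seq_along(lab))] <- 1
  P
}

#' Whole-volume inference by sliding-window patch aggregation
#'
#' Splits the (preprocessed) volume into `depth`-slice patches along z,
#' predicts class probabilities per patch, averages the probabilities of
#' overlapping patches voxel-wise (uniform weighting), and takes the argmax
#' over the 4 classes (ties break to the lowest class index).
#'
#' @param net a `dense_unet` or `oracle_net`.
#' @param v a [ct_volume], already rescaled/cropped to the network's
#'   in-plane size.
#' @param depth patch depth in slices.
#' @param stride_z z stride between patches.
#' @return a [class_mask] aligned to `v`.
#' @export
predict_volume <- function(net, v, depth = 64, stride_z = 32) {
  stopifnot(inherits(v, "ct_volume"))
  d <- dim(v$voxels)
  patches <- sample_patches(v, depth = depth, stride_z = stride_z)
  nz_eff <- max(d[1], depth)
  psum <- matrix(0, 4, nz_eff * d[2] * d[3])
  cnt <- numeric(nz_eff * d[2] * d[3])
  plane <- d[2] * d[3]
  for (p in patches) {
    P <- predict_patch(net, p$data, z_offset = p$z_offset)
    # voxel indices of this slab in the full volume (z-major layout)
    zi <- p$z_offset + seq_len(dim(p$data)[1])
    idx <- as.vector(outer(zi, (seq_len(plane) - 1L) * nz_eff, `+`))
    psum[, idx] <- psum[, idx] + P
    cnt[idx] <- cnt[idx] + 1
  }
  stopifnot(all(cnt > 0))
  avg <- psum / rep(cnt, each = 4)
  lab <- argmax_labels(avg)
  lab <- array(lab, dim = c(nz_eff, d[2], d[3]))[seq_len(d[1]), , , drop = FALSE]
  class_mask(lab, v$spacing)
}

#' @export
predict.dense_unet <- function(object, newdata, depth = 64, stride_z = 32, ...) {
  predict_volume(object, newdata, depth = depth, stride_z = stride_z)
}

#' Test-scale synthetic training set for the dense U-net
#'
#' Builds the small training corpus used for learning-sanity checks: three
#' training phantoms and one held-out phantom, each a 4-thoracic +
#' 2-lumbar column in a 156 x 64 x 64 volume at (1, 2, 2) mm spacing with
#' the generator's default attenuations and noise, cut into 16 x 64 x 64
#' sliding-window patches (z stride 11, 14 per volume, 42 in total). The
#' held-out phantom supplies both whole-volume evaluation data and a small
#' validation patch set for the monitored Dice metric.
#'
#' @param n_volumes number of training phantoms.
#' @param depth patch depth in slices.
#' @param stride_z patch stride in slices.
#' @param seed base RNG seed (training phantoms use `seed + 1 ..`,
#'   validation uses `seed + 1000`).
#' @return list with `patches`, `truths`, `val_patches`, `val_truths`,
#'   and `val_phantom` (the held-out `phantom_sample`).
#' @export
synthetic_training_set <- function(n_volumes = 3, depth = 16, stride_z = 11,
                                   seed = 1) {
  mk <- function(s) generate_phantom(phantom_spec(
    n_thoracic = 4, n_lumbar = 2, volume_shape = c(156, 64, 64), seed = s))
  patches <- list(); truths <- list()
  for (i in seq_len(n_volumes)) {
    ph <- mk(seed + i)
    pp <- sample_patches(ph$volume, depth = depth, stride_z = stride_z)
    tt <- sample_patches(ph$class_mask, depth = depth, stride_z = stride_z)
    patches <- c(patches, lapply(pp, `[[`, "data"))
    truths <- c(truths, lapply(tt, `[[`, "data"))
  }
  val_ph <- mk(seed + 1000)
  vp <- sample_patches(val_ph$volume, depth = depth, stride_z = depth)
  vt <- sample_patches(val_ph$class_mask, depth = depth, stride_z = depth)
  keep <- unique(round(seq(1, length(vp), length.out = min(4, length(vp)))))
  list(patches = patches, truths = truths,
       val_patches = lapply(vp[keep], `[[`, "data"),
       val_truths = lapply(vt[keep], `[[`, "data"),
       val_phantom = val_ph)
}

#' Mean per-instance Dice of a predicted class mask against phantom truth
#'
#' Each ground-truth vertebra is matched to the predicted foreground
#' component with maximal voxel overlap (class-agnostic, since instance
#' extraction binarizes the foreground); unmatched vertebrae score 0.
#'
#' @param pred a [class_mask] prediction.
#' @param sample the `phantom_sample` providing instance truth.
#' @param min_voxels speckle threshold for instance extraction.
#' @return list with `per_instance` (named numeric) and `mean`.
#' @export
per_instance_dice <- function(pred, sample, min_voxels = 100) {
  inst <- extract_components(pred, min_voxels = min_voxels)
  d <- vapply(sample$instance_truth, function(tr) {
    if (!length(inst)) return(0)
    ov <- vapply(inst, function(pi) length(intersect(pi$voxels, tr$voxels)), 0)
    if (max(ov) == 0) return(0)
    dice_coefficient(inst[[which.max(ov)]]$voxels, tr$voxels)
  }, 0)
  names(d) <- vapply(sample$instance_truth, `[[`, "", "name")
  list(per_instance = d, mean = mean(d))
}
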