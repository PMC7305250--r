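#' Configuration of the 3D dense-connected U-net
#'
#' The segmentation network is a symmetric encoder--decoder (U-net) whose
#' convolutional stack at every level is a dense block: each 3x3x3
#' convolution receives the concatenation of the block input and all previous
#' layer outputs and emits `growth_rate` new channels, and the block output
#' goes through a 1x1x1 convolution to reduce dimensions. Downsampling is
#' 2x2x2 max pooling, upsampling is nearest-neighbor; skip connections
#' concatenate encoder features into the decoder, followed by a 1x1x1
#' channel reduction. The head is a 1x1x1 convolution to 4 classes with a
#' per-voxel softmax.
#'
#' `layers_per_dense_block` lists the number of convolutions per dense block,
#' encoder top-to-bottom then decoder bottom-to-top (`2 * n_levels - 1`
#' entries). Per-level depths are not standardized for this architecture, so
#' the default `(2,3,4,4,4,3,2)` is config-exposed rather than fixed.
#'
#' @param n_levels number of resolution levels (>= 2).
#' @param layers_per_dense_block integer vector, length `2 * n_levels - 1`.
#' @param growth_rate channels added by each dense-block layer (default 8).
#' @param base_channels channels after every 1x1x1 reduction.
#' @param n_classes number of output classes; the vertebral task uses 4.
#' @param input_scale multiplicative input normalization applied to HU
#'   values before the first convolution (default 1/1000, mapping air to -1).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(n_levels = 4,
                        layers_per_dense_block = c(2, 3, 4, 4, 4, 3, 2),
                        growth_rate = 8, base_channels = 16, n_classes = 4,
                        input_scale = 1e-3) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("unet_config: n_levels must be >= 2")
  if (length(layers_per_dense_block) != 2 * n_levels - 1)
    stop("unet_config: layers_per_dense_block must have length 2*n_levels-1 = ",
         2 * n_levels - 1)
  if (growth_rate <= 0) stop("unet_config: growth_rate must be positive")
  if (n_classes != 4)
    stop("unet_config: the vertebral segmentation task is 4-class")
  structure(list(n_levels = n_levels,
                 layers_per_dense_block = as.integer(layers_per_dense_block),
                 growth_rate = as.integer(growth_rate),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 kernel = c(3L, 3L, 3L),
                 input_scale = input_scale),
            class = "unet_config")
}

#' Build a 3D dense U-net with randomly initialized weights
#'
#' Weights use He initialization (sd `sqrt(2 / fan_in)`); biases start at
#' zero. The same seed reproduces the same initialization bit for bit.
#'
#' @param cfg a [unet_config].
#' @param in_channels input channels (1 for CT volumes).
#' @param seed RNG seed for initialization.
#' @return object of class `dense_unet` holding `cfg` and the parameter list.
#' @export
build_dense_unet <- function(cfg, in_channels = 1, seed = 1) {
  stopifnot(inherits(cfg, "unet_config"))
  L <- cfg$n_levels; dpb <- cfg$layers_per_dense_block
  g <- cfg$growth_rate; m <- cfg$base_channels
  he3 <- function(co, ci) array(rnorm(co * ci * 27, 0, sqrt(2 / (ci * 27))),
                                c(co, ci, 27))
  he1 <- function(co, ci) matrix(rnorm(co * ci, 0, sqrt(2 / ci)), co, ci)
  params <- list()
  with_seed(seed, {
    for (l in seq_len(L)) {
      cc <- if (l == 1) in_channels else m
      for (j in seq_len(dpb[l])) {
        params[[sprintf("enc%d_conv%d_W", l, j)]] <- he3(g, cc)
        params[[sprintf("enc%d_conv%d_b", l, j)]] <- numeric(g)
        cc <- cc + g
      }
      params[[sprintf("enc%d_bott_W", l)]] <- he1(m, cc)
      params[[sprintf("enc%d_bott_b", l)]] <- numeric(m)
    }
    for (l in rev(seq_len(L - 1))) {
      params[[sprintf("dec%d_red_W", l)]] <- he1(m, 2L * m)
      params[[sprintf("dec%d_red_b", l)]] <- numeric(m)
      cc <- m
      for (j in seq_len(dpb[2L * L - l])) {
        params[[sprintf("dec%d_conv%d_W", l, j)]] <- he3(g, cc)
        params[[sprintf("dec%d_conv%d_b", l, j)]] <- numeric(g)
        cc <- cc + g
      }
      params[[sprintf("dec%d_bott_W", l)]] <- he1(m, cc)
      params[[sprintf("dec%d_bott_b", l)]] <- numeric(m)
    }
    params$final_W <- he1(cfg$n_classes, m)
    params$final_b <- numeric(cfg$n_classes)
  })
  structure(list(cfg = cfg, params = params, in_channels = as.integer(in_channels),
                 history = NULL),
            class = "dense_unet")
}

#' @export
print.dense_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<dense_unet> %d levels, growth %d, base %d, %d parameters%s\n",
              x$cfg$n_levels, x$cfg$growth_rate, x$cfg$base_channels, np,
              if (is.null(x$history)) " (untrained)"
              else sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_cols <- function(Z) {
  mx <- apply(Z, 2, max)
  E <- exp(Z - rep(mx, each = nrow(Z)))
  E / rep(colSums(E), each = nrow(Z))
}

check_divisible <- function(dims, L) {
  f <- 2^(L - 1)
  if (any(dims %% f != 0))
    stop(sprintf("dense_unet: input dims (%s) must be divisible by 2^(n_levels-1) = %d",
                 paste(dims, collapse = "x"), f), call. = FALSE)
}

# dense block forward: returns the concatenated feature matrix (block input
# rows first, then each layer's ReLU output), which is all the backward pass
# needs (inputs to layer j are rows 1..c0+(j-1)*g; ReLU masks come from the
# stored activations themselves).
dense_block_fw <- function(X, prefix, d, params, dims) {
  feats <- X
  for (j in seq_len(d)) {
    Y <- conv3d_fw_cpp(feats,
                       params[[sprintf("%s_conv%d_W", prefix, j)]],
                       params[[sprintf("%s_conv%d_b", prefix, j)]], as.integer(dims))
    feats <- rbind(feats, relu(Y))
  }
  feats
}

dense_block_bw <- function(feats, dFeats, prefix, d, c0, g, params, dims, grads) {
  for (j in rev(seq_len(d))) {
    rows_in <- seq_len(c0 + (j - 1) * g)
    rows_a <- c0 + (j - 1) * g + seq_len(g)
    A <- feats[rows_a, , drop = FALSE]
    dY <- dFeats[rows_a, , drop = FALSE] * (A > 0)
    bw <- conv3d_bw_cpp(feats[rows_in, , drop = FALSE], dY,
                        params[[sprintf("%s_conv%d_W", prefix, j)]],
                        as.integer(dims))
    grads[[sprintf("%s_conv%d_W", prefix, j)]] <- bw$dW
    grads[[sprintf("%s_conv%d_b", prefix, j)]] <- as.numeric(bw$db)
    dFeats <- dFeats[rows_in, , drop = FALSE] + bw$dX
  }
  list(dX = dFeats[seq_len(c0), , drop = FALSE], grads = grads)
}

bottleneck_fw <- function(X, W, b) relu(W %*% X + b)

# 0-based-free nearest-neighbor upsample map: fine voxel -> coarse voxel index
upsample_map <- function(fine_dims) {
  nz <- fine_dims[1]; ny <- fine_dims[2]; nx <- fine_dims[3]
  zv <- rep.int(0:(nz - 1), ny * nx)
  yv <- rep.int(rep(0:(ny - 1), each = nz), nx)
  xv <- rep(0:(nx - 1), each = nz * ny)
  (zv %/% 2) + (nz %/% 2) * ((yv %/% 2) + (ny %/% 2) * (xv %/% 2)) + 1L
}

#' Forward pass of the dense U-net
#'
#' @param net a `dense_unet`.
#' @param patch 3D numeric array `(z, y, x)` of HU values (dims divisible by
#'   `2^(n_levels-1)`).
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `prob` (`n_classes` x n_voxels matrix of class
#'   probabilities; columns sum to 1), `dims`, and (if requested) `cache`.
#' @export
unet_forward <- function(net, patch, keep_cache = FALSE) {
  cfg <- net$cfg; p <- net$params
  L <- cfg$n_levels; dpb <- cfg$layers_per_dense_block; m <- cfg$base_channels
  dims <- dim(patch)
  check_divisible(dims, L)
  X <- matrix(as.numeric(patch) * cfg$input_scale, nrow = 1)
  cache <- list(dims = dims)
  lev_dims <- dims
  B <- vector("list", L)      # bottleneck outputs (skips)
  pool_arg <- vector("list", L)
  feats_enc <- vector("list", L)
  for (l in seq_len(L)) {
    feats <- dense_block_fw(X, sprintf("enc%d", l), dpb[l], p, lev_dims)
    Bl <- bottleneck_fw(feats, p[[sprintf("enc%d_bott_W", l)]],
                        p[[sprintf("enc%d_bott_b", l)]])
    feats_enc[[l]] <- if (keep_cache) feats else NULL
    B[[l]] <- Bl
    if (l < L) {
      pool <- maxpool3d_fw_cpp(Bl, as.integer(lev_dims))
      pool_arg[[l]] <- pool$argmax
      X <- pool$Y
      lev_dims <- lev_dims %/% 2L
    }
  }
  up <- B[[L]]
  dec_cache <- vector("list", L)
  for (l in rev(seq_len(L - 1))) {
    lev_dims <- dims %/% (2L^(l - 1L))
    umap <- upsample_map(lev_dims)
    U <- up[, umap, drop = FALSE]
    Cat <- rbind(U, B[[l]])
    Rl <- bottleneck_fw(Cat, p[[sprintf("dec%d_red_W", l)]],
                        p[[sprintf("dec%d_red_b", l)]])
    featsd <- dense_block_fw(Rl, sprintf("dec%d", l), dpb[2L * L - l], p,
                             lev_dims)
    up <- bottleneck_fw(featsd, p[[sprintf("dec%d_bott_W", l)]],
                        p[[sprintf("dec%d_bott_b", l)]])
    if (keep_cache)
      dec_cache[[l]] <- list(Cat = Cat, R = Rl, feats = featsd, out = up,
                             umap = umap)
  }
  Z <- p$final_W %*% up + p$final_b
  P <- softmax_cols(Z)
  out <- list(prob = P, dims = dims)
  if (keep_cache) {
    cache$feats_enc <- feats_enc; cache$B <- B; cache$pool_arg <- pool_arg
    cache$dec <- dec_cache; cache$head_in <- up; cache$P <- P
    out$cache <- cache
  }
  out
}

#' Soft Dice loss over the foreground classes
#'
#' `loss = 1 - mean_c (2 * sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)`
#' over the three vertebral classes (background excluded, as is standard when
#' background dominates the voxel count); `eps = 1e-5`.
#'
#' @param prob class-probability matrix (`n_classes` x n_voxels) or the
#'   result of [unet_forward()].
#' @param truth integer vector/array of true labels 0..3, same voxel order.
#' @param eps numerical smoothing term.
#' @return scalar loss in `[0, 1 + eps]`.
#' @export
dice_loss <- function(prob, truth, eps = 1e-5) {
  if (is.list(prob)) prob <- prob$prob
  t <- as.integer(truth)
  stopifnot(ncol(prob) == length(t))
  d <- vapply(1:3, function(c) {
    tc <- t == c
    (2 * sum(prob[c + 1, ] * tc) + eps) / (sum(prob[c + 1, ]) + sum(tc) + eps)
  }, 0)
  1 - mean(d)
}

# gradient of dice_loss w.r.t. the probability matrix
dice_loss_grad <- function(prob, truth, eps = 1e-5) {
  t <- as.integer(truth)
  dP <- matrix(0, nrow(prob), ncol(prob))
  for (c in 1:3) {
    tc <- as.numeric(t == c)
    num <- 2 * sum(prob[c + 1, ] * tc) + eps
    den <- sum(prob[c + 1, ]) + sum(tc) + eps
    dP[c + 1, ] <- -(1 / 3) * (2 * tc * den - num) / den^2
  }
  dP
}

#' Backward pass: parameter gradients of the Dice loss
#'
#' @param net a `dense_unet`.
#' @param fw result of `unet_forward(net, patch, keep_cache = TRUE)`.
#' @param truth integer labels 0..3 in voxel order.
#' @return named list of gradients matching `net$params`.
#' @export
unet_backward <- function(net, fw, truth) {
  cfg <- net$cfg; p <- net$params; cache <- fw$cache
  if (is.null(cache)) stop("unet_backward: forward pass must keep_cache")
  L <- cfg$n_levels; dpb <- cfg$layers_per_dense_block
  g <- cfg$growth_rate; m <- cfg$base_channels
  dims <- cache$dims
  P <- cache$P
  dP <- dice_loss_grad(P, truth)
  dZ <- P * (dP - rep(colSums(dP * P), each = nrow(P)))
  grads <- list()
  grads$final_W <- dZ %*% t(cache$head_in)
  grads$final_b <- rowSums(dZ)
  dup <- t(p$final_W) %*% dZ          # grad w.r.t. decoder output at level 1
  for (l in seq_len(L - 1)) {          # decoder levels, finest first
    dc <- cache$dec[[l]]
    lev_dims <- dims %/% (2L^(l - 1L))
    dOut <- dup * (dc$out > 0)
    grads[[sprintf("dec%d_bott_W", l)]] <- dOut %*% t(dc$feats)
    grads[[sprintf("dec%d_bott_b", l)]] <- rowSums(dOut)
    dFeats0 <- t(p[[sprintf("dec%d_bott_W", l)]]) %*% dOut
    bb <- dense_block_bw(dc$feats, dFeats0, sprintf("dec%d", l), dpb[2L * L - l],
                         m, g, p, lev_dims, grads)
    grads <- bb$grads
    dR <- bb$dX * (dc$R > 0)
    grads[[sprintf("dec%d_red_W", l)]] <- dR %*% t(dc$Cat)
    grads[[sprintf("dec%d_red_b", l)]] <- rowSums(dR)
    dCat <- t(p[[sprintf("dec%d_red_W", l)]]) %*% dR
    dU <- dCat[seq_len(m), , drop = FALSE]
    dSkip <- dCat[m + seq_len(m), , drop = FALSE]
    # upsample backward: sum gradients of the fine voxels over each parent
    dcoarse <- t(rowsum(t(dU), group = dc$umap))
    cache$dB[[l]] <- dSkip               # into the encoder skip
    dup <- dcoarse                       # continues to the coarser decoder level
  }
  # encoder, bottom level first: dup currently holds grad at enc L bottleneck out
  dB_enc <- cache$dB
  dX_pooled <- NULL
  for (l in rev(seq_len(L))) {
    lev_dims <- dims %/% (2L^(l - 1L))
    dBl <- if (l == L) dup else dB_enc[[l]]
    if (l < L && !is.null(dX_pooled)) {
      dBl <- dBl + maxpool3d_bw_cpp(dX_pooled, cache$pool_arg[[l]],
                                    prod(lev_dims))
    }
    feats <- cache$feats_enc[[l]]
    Bl <- cache$B[[l]]
    dBl <- dBl * (Bl > 0)
    grads[[sprintf("enc%d_bott_W", l)]] <- dBl %*% t(feats)
    grads[[sprintf("enc%d_bott_b", l)]] <- rowSums(dBl)
    dFeats <- t(p[[sprintf("enc%d_bott_W", l)]]) %*% dBl
    c0 <- if (l == 1) net$in_channels else m
    bb <- dense_block_bw(feats, dFeats, sprintf("enc%d", l), dpb[l], c0, g,
                         p, lev_dims, grads)
    grads <- bb$grads
    dX_pooled <- bb$dX        # grad w.r.t. this level's input (pooled B of l-1)
  }
  grads
}
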