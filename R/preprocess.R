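#' Rescale axial slices to a target in-plane pixel size
#'
#' Every axial slice is resampled to `target_xy_mm` x `target_xy_mm` pixels;
#' the z axis is never touched. Images use bilinear interpolation (separable
#' row/column linear weights with pixel-center alignment); masks must use
#' nearest-neighbor so labels stay integral. Output size along each in-plane
#' axis is `round(n * spacing / target)`.
#'
#' @param v a [ct_volume] or [class_mask].
#' @param target_xy_mm target pixel size in mm (both row and col).
#' @param method `"bilinear"` (default for volumes) or `"nearest"` (forced
#'   for masks).
#' @return the rescaled object of the same class, with updated spacing.
#' @export
rescale_axial <- function(v, target_xy_mm = 2, method = NULL) {
  stopifnot(target_xy_mm > 0)
  is_mask <- inherits(v, "class_mask")
  if (is.null(method)) method <- if (is_mask) "nearest" else "bilinear"
  if (is_mask && method != "nearest")
    stop("rescale_axial: masks must use nearest-neighbor resampling", call. = FALSE)
  arr <- if (is_mask) v$labels else v$voxels
  d <- dim(arr)
  sp <- v$spacing
  if (d[2] <= 1 || d[3] <= 1)
    stop("rescale_axial: degenerate slice (<= 1 pixel along an axis)", call. = FALSE)
  if (abs(sp[2] - target_xy_mm) < 1e-9 && abs(sp[3] - target_xy_mm) < 1e-9)
    return(v)
  ny <- max(2L, as.integer(round(d[2] * sp[2] / target_xy_mm)))
  nx <- max(2L, as.integer(round(d[3] * sp[3] / target_xy_mm)))
  Ry <- resample_matrix(d[2], ny, sp[2], target_xy_mm, method)
  Rx <- resample_matrix(d[3], nx, sp[3], target_xy_mm, method)
  out <- array(if (is_mask) 0L else 0, dim = c(d[1], ny, nx))
  for (z in seq_len(d[1])) {
    sl <- Ry %*% arr[z, , ] %*% t(Rx)
    out[z, , ] <- if (is_mask) as.integer(round(sl)) else sl
  }
  newsp <- c(sp[1], target_xy_mm, target_xy_mm)
  if (is_mask) class_mask(out, newsp) else ct_volume(out, newsp)
}

# Sparse-in-spirit 1D resampling operator (n_out x n_in), pixel-center
# convention: output center j maps to input coordinate
# ((j - 0.5) * target) / src - 0.5 + 0.5 (1-based), clamped at the edges.
resample_matrix <- function(n_in, n_out, src_mm, target_mm, method) {
  pos <- ((seq_len(n_out) - 0.5) * target_mm) / src_mm + 0.5  # 1-based
  pos <- pmin(pmax(pos, 1), n_in)
  R <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    i <- pmin(pmax(round(pos), 1), n_in)
    R[cbind(seq_len(n_out), i)] <- 1
  } else {
    lo <- pmin(floor(pos), n_in - 1)
    w <- pos - lo
    R[cbind(seq_len(n_out), lo)] <- R[cbind(seq_len(n_out), lo)] + (1 - w)
    R[cbind(seq_len(n_out), lo + 1)] <- R[cbind(seq_len(n_out), lo + 1)] + w
  }
  R
}

#' Locate the body center on an axial slice by thresholding
#'
#' Thresholds the slice at `hu_threshold` (default -200 HU separates soft
#' tissue from air robustly), labels 8-connected 2D components, and returns
#' the centroid of the largest. If nothing exceeds the threshold the
#' geometric slice center is returned with `degenerate = TRUE`.
#'
#' @param slice 2D numeric matrix of HU values (rows x cols).
#' @param hu_threshold HU threshold for body vs air.
#' @return list with `center` `(row, col)` (fractional, 1-based) and
#'   `degenerate` flag.
#' @export
find_body_center <- function(slice, hu_threshold = -200) {
  stopifnot(is.matrix(slice), length(slice) > 0)
  fg <- slice > hu_threshold
  if (!any(fg)) {
    return(list(center = c(row = (nrow(slice) + 1) / 2,
                           col = (ncol(slice) + 1) / 2),
                degenerate = TRUE))
  }
  # reuse the 3D labeler with a singleton z axis (26-conn == 8-conn in plane)
  lab <- cc_label_cpp(as.integer(fg), c(1L, nrow(slice), ncol(slice)), TRUE)
  big <- which.max(tabulate(lab))
  idx <- which(matrix(lab == big, nrow(slice)), arr.ind = TRUE)
  list(center = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
       degenerate = FALSE)
}

#' Crop every axial slice to a square window around a center
#'
#' The window is `size x size`, positioned so that `round(center)` sits at
#' its middle; where it exceeds the volume bounds the output is padded with
#' air (-1000 HU for volumes, 0 for masks). The crop offset is recorded in
#' attribute `crop_offset` (1-based start row/col in the original grid) so
#' masks produced on the crop can be projected back with
#' [backproject_mask()].
#'
#' @param v a [ct_volume] or [class_mask].
#' @param center numeric(2) `(row, col)`, 1-based.
#' @param size window side in pixels (default 160).
#' @return cropped object with attribute `crop_offset`.
#' @export
crop_centered <- function(v, center, size = 160) {
  stopifnot(size > 0)
  is_mask <- inherits(v, "class_mask")
  arr <- if (is_mask) v$labels else v$voxels
  d <- dim(arr)
  start <- round(center) - size %/% 2
  rows <- seq.int(start[1], start[1] + size - 1L)
  cols <- seq.int(start[2], start[2] + size - 1L)
  pad <- if (is_mask) 0L else -1000
  out <- array(pad, dim = c(d[1], size, size))
  rok <- which(rows >= 1 & rows <= d[2])
  cok <- which(cols >= 1 & cols <= d[3])
  out[, rok, cok] <- arr[, rows[rok], cols[cok]]
  res <- if (is_mask) class_mask(out, v$spacing) else ct_volume(out, v$spacing)
  attr(res, "crop_offset") <- c(row = start[1], col = start[2])
  res
}

#' Project a mask computed on a crop back to the original grid
#'
#' @param m a [class_mask] produced on a [crop_centered()] output.
#' @param crop_offset the `crop_offset` attribute of the crop.
#' @param orig_dim integer(3) dims of the original volume.
#' @return a [class_mask] on the original grid (0 outside the crop).
#' @export
backproject_mask <- function(m, crop_offset, orig_dim) {
  stopifnot(inherits(m, "class_mask"))
  d <- dim(m$labels)
  out <- array(0L, dim = orig_dim)
  rows <- seq.int(crop_offset[1], crop_offset[1] + d[2] - 1L)
  cols <- seq.int(crop_offset[2], crop_offset[2] + d[3] - 1L)
  rok <- which(rows >= 1 & rows <= orig_dim[2])
  cok <- which(cols >= 1 & cols <= orig_dim[3])
  out[, rows[rok], cols[cok]] <- m$labels[, rok, cok]
  class_mask(out, m$spacing)
}

#' Sample sliding-window 3D patches along z
#'
#' Patches are `depth` slices deep at the full in-plane size; consecutive
#' z offsets differ by `stride_z` and the final patch is clamped so the last
#' slice is covered. A volume with fewer than `depth` slices yields a single
#' patch padded with air (-1000 HU) and flagged.
#'
#' @param v a [ct_volume] (or [class_mask]; padding is then 0).
#' @param depth patch depth in slices (default 64).
#' @param stride_z offset between consecutive patches, slices.
#' @return list of patches; each has fields `data` (3D array) and
#'   `z_offset` (0-based offset of the patch's first slice), plus `padded`
#'   when zero-padding was needed. Attribute `offsets` lists all offsets.
#' @export
sample_patches <- function(v, depth = 64, stride_z = 32) {
  stopifnot(depth >= 1, stride_z >= 1)
  if (stride_z > depth)
    stop("sample_patches: stride_z must not exceed depth (slab union must cover all slices)",
         call. = FALSE)
  is_mask <- inherits(v, "class_mask")
  arr <- if (is_mask) v$labels else v$voxels
  d <- dim(arr)
  if (d[1] < depth) {
    pad <- array(if (is_mask) 0L else -1000, dim = c(depth, d[2], d[3]))
    pad[seq_len(d[1]), , ] <- arr
    p <- list(list(data = pad, z_offset = 0L, padded = TRUE))
    attr(p, "offsets") <- 0L
    return(p)
  }
  offs <- seq.int(0L, d[1] - depth, by = stride_z)
  if (tail(offs, 1) != d[1] - depth) offs <- c(offs, d[1] - depth)
  p <- lapply(offs, function(o)
    list(data = arr[(o + 1):(o + depth), , , drop = FALSE],
         z_offset = as.integer(o), padded = FALSE))
  attr(p, "offsets") <- as.integer(offs)
  p
}

#' Random in-plane translation and rotation of a patch (with its mask)
#'
#' Draws a translation uniform in `[-translate_vox, translate_vox]` per axis
#' and a rotation uniform in `[-rotate_deg, rotate_deg]` about the slice
#' center, and applies the same transform to every slice of the image
#' (bilinear) and of the mask (nearest-neighbor). Seeded for determinism.
#' Out-of-frame samples take the background values (-1000 HU / label 0).
#'
#' @param image 3D array `(z, y, x)` of HU values.
#' @param mask optional 3D integer array aligned to `image`.
#' @param translate_vox maximum absolute translation, voxels (default 8).
#' @param rotate_deg maximum absolute rotation, degrees (default 10).
#' @param seed integer seed; same seed, same transform.
#' @param params optional fixed transform `list(dy, dx, theta_deg)`,
#'   bypassing the random draw.
#' @return list with `image`, `mask` (or NULL) and `params`
#'   (`dy`, `dx`, `theta_deg`).
#' @export
augment_patch <- function(image, mask = NULL, translate_vox = 8,
                          rotate_deg = 10, seed = NULL, params = NULL) {
  d <- dim(image)
  stopifnot(length(d) == 3)
  par <- if (!is.null(params)) {
    list(dy = params$dy, dx = params$dx, theta = params$theta_deg * pi / 180)
  } else {
    with_seed(seed, list(dy = runif(1, -translate_vox, translate_vox),
                         dx = runif(1, -translate_vox, translate_vox),
                         theta = runif(1, -rotate_deg, rotate_deg) * pi / 180))
  }
  if (par$dy == 0 && par$dx == 0 && par$theta == 0)
    return(list(image = image, mask = mask,
                params = list(dy = 0, dx = 0, theta_deg = 0)))
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  # inverse map: for each output pixel, the source location
  gy <- rep(seq_len(d[2]), times = d[3]) - cy
  gx <- rep(seq_len(d[3]), each = d[2]) - cx
  ct <- cos(-par$theta); st <- sin(-par$theta)
  sy <- ct * (gy - par$dy) - st * (gx - par$dx) + cy
  sx <- st * (gy - par$dy) + ct * (gx - par$dx) + cx
  out_img <- warp_slices(image, sy, sx, bilinear = TRUE, fill = -1000)
  out_msk <- if (!is.null(mask))
    warp_slices(mask, sy, sx, bilinear = FALSE, fill = 0L) else NULL
  list(image = out_img, mask = out_msk,
       params = list(dy = par$dy, dx = par$dx, theta_deg = par$theta * 180 / pi))
}

warp_slices <- function(arr, sy, sx, bilinear, fill) {
  d <- dim(arr)
  inb <- sy >= 1 & sy <= d[2] & sx >= 1 & sx <= d[3]
  out <- array(fill, dim = d)
  if (bilinear) {
    y0 <- pmin(pmax(floor(sy), 1), d[2] - 1); x0 <- pmin(pmax(floor(sx), 1), d[3] - 1)
    wy <- sy - y0; wx <- sx - x0
    i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
    i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
    for (z in seq_len(d[1])) {
      sl <- arr[z, , ]
      val <- (1 - wy) * (1 - wx) * sl[i00] + (1 - wy) * wx * sl[i01] +
        wy * (1 - wx) * sl[i10] + wy * wx * sl[i11]
      val[!inb] <- fill
      out[z, , ] <- matrix(val, d[2], d[3])
    }
  } else {
    yn <- pmin(pmax(round(sy), 1), d[2]); xn <- pmin(pmax(round(sx), 1), d[3])
    idx <- cbind(yn, xn)
    for (z in seq_len(d[1])) {
      sl <- arr[z, , ]
      val <- sl[idx]
      val[!inb] <- fill
      out[z, , ] <- matrix(val, d[2], d[3])
    }
  }
  if (is.integer(arr)) storage.mode(out) <- "integer"
  out
}
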