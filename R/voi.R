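#' Middle-slice range of a vertebra for the cylindrical VOI
#'
#' The trabecular VOI is a 9-mm-high cylinder; at a slice thickness of
#' `slice_thickness_mm` this spans `n = round(9 / slice_thickness_mm)`
#' slices, centered on the vertebra's middle slice. With `z_extent`
#' `[z_min, z_max]` (inclusive slice indices), the middle slice is
#' `z_mid = floor((z_min + z_max) / 2)` and the range starts at
#' `z_mid - floor(n/2)`.
#'
#' @param inst a `vertebra_instance` (see [extract_components()]), or any
#'   list with a `z_extent` field.
#' @param voi_height_mm cylinder height in mm (default 9).
#' @param slice_thickness_mm z spacing of the volume in mm.
#' @return integer vector of `n` consecutive slice indices.
#' @examples
#' middle_slices(list(z_extent = c(10, 30)), slice_thickness_mm = 1)  # 16..24
#' @export
middle_slices <- function(inst, voi_height_mm = 9, slice_thickness_mm = 1) {
  stopifnot(voi_height_mm > 0, slice_thickness_mm > 0)
  n <- max(1L, as.integer(round(voi_height_mm / slice_thickness_mm)))
  ze <- inst$z_extent
  span <- ze[2] - ze[1] + 1
  if (span < n)
    stop(sprintf("vertebra %s too thin for VOI: spans %d slices, need %d",
                 if (!is.null(inst$name) && !is.na(inst$name)) inst$name else "?",
                 span, n), call. = FALSE)
  z_mid <- floor((ze[1] + ze[2]) / 2)
  z0 <- z_mid - n %/% 2
  seq.int(z0, z0 + n - 1L)
}

#' Fit the elliptical trabecular VOI on a vertebra's middle slice
#'
#' The VOI cross-section is an axis-aligned ellipse centered on the centroid
#' of the vertebral-body (VB) region of the middle slice. Its size is fixed
#' by two ratios: the ellipse area is `area_frac` (default 30%) of the VB
#' region area, and the short semi-axis is `short_frac` (default 20%) of the
#' maximum row length of the region -- the longest contiguous run of region
#' pixels within any single image row, in mm. The long semi-axis follows from
#' the area: `semi_long = area_frac * A / (pi * semi_short)`. The short axis
#' lies along the row (anterior--posterior) direction. These margins keep the
#' ellipse inside the trabecular compartment for cortical shells up to about
#' 1 mm thick.
#'
#' @param region logical matrix (rows x cols): the VB region on the middle
#'   slice.
#' @param spacing_yx numeric(2), in-plane voxel spacing `(row, col)` in mm.
#' @param area_frac ellipse area as a fraction of the VB region area.
#' @param short_frac short semi-axis as a fraction of the maximum row length.
#' @return An object of class `ellipse_voi`: `center` (fractional row/col
#'   voxel indices), `semi_short`, `semi_long` (mm), `area_mm2`,
#'   `max_row_mm`, the two fractions, and `warnings`.
#' @examples
#' disk <- outer((-60:60)^2, (-60:60)^2, `+`) <= 50^2
#' v <- fit_ellipse_voi(disk, c(1, 1))
#' pi * v$semi_short * v$semi_long / v$area_mm2  # exactly 0.30
#' @export
fit_ellipse_voi <- function(region, spacing_yx = c(1, 1),
                            area_frac = 0.30, short_frac = 0.20) {
  stopifnot(is.matrix(region), area_frac > 0, short_frac > 0)
  region <- region != 0
  if (!any(region))
    stop("fit_ellipse_voi: empty middle-slice region", call. = FALSE)
  sy <- spacing_yx[1]; sx <- spacing_yx[2]
  idx <- which(region, arr.ind = TRUE)
  center <- c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  area_mm2 <- nrow(idx) * sy * sx
  max_row_vox <- max(apply(region, 1, longest_run))
  max_row_mm <- max_row_vox * sx
  semi_short <- short_frac * max_row_mm
  semi_long <- area_frac * area_mm2 / (pi * semi_short)
  warnings <- character()
  if (semi_long < semi_short) {
    tmp <- semi_short; semi_short <- semi_long; semi_long <- tmp
    warnings <- c(warnings, "axes_swapped")
    warning("fit_ellipse_voi: inferred long semi-axis shorter than short; axes swapped",
            call. = FALSE)
  }
  # containment in the region bounding box (mm, voxel centers)
  bb_row <- (range(idx[, 1]) - center["row"]) * sy
  bb_col <- (range(idx[, 2]) - center["col"]) * sx
  if (semi_short > min(abs(bb_row)) || semi_long > min(abs(bb_col))) {
    warnings <- c(warnings, "ellipse_exceeds_bbox")
    warning("fit_ellipse_voi: ellipse exceeds region bounding box (non-convex region?)",
            call. = FALSE)
  }
  structure(list(vertebra = NA_character_, middle_slice = NA_integer_,
                 slice_range = NULL, center = center,
                 semi_short = semi_short, semi_long = semi_long,
                 area_mm2 = area_mm2, max_row_mm = max_row_mm,
                 area_frac = area_frac, short_frac = short_frac,
                 spacing_yx = c(sy, sx), warnings = warnings),
            class = "ellipse_voi")
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(as.logical(x))
  max(r$lengths[r$values])
}

#' Place the full cylindrical VOI for a named vertebra instance
#'
#' Combines [middle_slices()] and [fit_ellipse_voi()]: takes a vertebra
#' instance (voxel set plus z extent), extracts its middle-slice 2D region,
#' fits the ellipse there, and attaches the 9-slice range.
#'
#' @param inst a `vertebra_instance` from [extract_components()] /
#'   [assign_names()].
#' @param dim integer(3) volume dims `(z, y, x)`.
#' @param spacing numeric(3) voxel spacing `(z, y, x)` in mm.
#' @param voi_height_mm cylinder height, mm.
#' @inheritParams fit_ellipse_voi
#' @return An `ellipse_voi` with `vertebra`, `middle_slice` and
#'   `slice_range` filled in.
#' @export
instance_voi <- function(inst, dim, spacing, voi_height_mm = 9,
                         area_frac = 0.30, short_frac = 0.20) {
  zr <- middle_slices(inst, voi_height_mm, spacing[1])
  z_mid <- floor((inst$z_extent[1] + inst$z_extent[2]) / 2)
  # 2D region of this instance on the middle slice
  vox <- inst$voxels
  coords <- arrayInd(vox, dim)
  on_mid <- coords[, 1] == z_mid
  if (!any(on_mid))
    stop("instance_voi: instance has no voxels on its middle slice", call. = FALSE)
  region <- matrix(FALSE, dim[2], dim[3])
  region[coords[on_mid, 2:3, drop = FALSE]] <- TRUE
  voi <- fit_ellipse_voi(region, spacing[2:3], area_frac, short_frac)
  voi$vertebra <- if (is.null(inst$name)) NA_character_ else inst$name
  voi$middle_slice <- z_mid
  voi$slice_range <- zr
  voi
}

#' Mean CT number inside a cylindrical elliptical VOI
#'
#' Averages the HU of every voxel whose in-plane center lies inside the
#' ellipse, over all slices of the VOI range (no partial-volume weighting).
#'
#' @param v a [ct_volume].
#' @param voi an `ellipse_voi` with `slice_range` set.
#' @return list with `mean_hu` and `n_voxels`.
#' @export
mean_ct <- function(v, voi) {
  stopifnot(inherits(v, "ct_volume"), inherits(voi, "ellipse_voi"))
  d <- dim(v$voxels)
  zr <- voi$slice_range
  if (is.null(zr)) stop("mean_ct: VOI has no slice range", call. = FALSE)
  if (min(zr) < 1 || max(zr) > d[1])
    stop("mean_ct: VOI slice range outside volume bounds", call. = FALSE)
  sy <- voi$spacing_yx[1]; sx <- voi$spacing_yx[2]
  ry <- (seq_len(d[2]) - voi$center["row"]) * sy / voi$semi_short
  rx <- (seq_len(d[3]) - voi$center["col"]) * sx / voi$semi_long
  inside <- outer(ry^2, rx^2, `+`) <= 1
  if (!any(inside))
    stop("mean_ct: rasterized ellipse contains no voxel centers", call. = FALSE)
  vals <- v$voxels[zr, , , drop = FALSE]
  vals <- matrix(vals, nrow = length(zr))[, as.vector(inside), drop = FALSE]
  list(mean_hu = mean(vals), n_voxels = length(vals))
}

#' @export
print.ellipse_voi <- function(x, ...) {
  cat(sprintf(
    "<ellipse_voi> %s: center (%.1f, %.1f) vox, semi-axes %.2f x %.2f mm, slices %s\n",
    ifelse(is.na(x$vertebra), "unnamed", x$vertebra),
    x$center[1], x$center[2], x$semi_short, x$semi_long,
    if (is.null(x$slice_range)) "unset"
    else sprintf("[%d..%d]", min(x$slice_range), max(x$slice_range))))
  invisible(x)
}

#' Tabulate VOI measurements for a set of instances
#'
#' @param vois list of `ellipse_voi` objects.
#' @param means list of results from [mean_ct()], parallel to `vois`.
#' @return data frame with one row per VOI (vertebra, z0, n_slices,
#'   center_row, center_col, semi_short, semi_long, n_voxels, mean_hu).
#' @export
voi_report <- function(vois, means) {
  stopifnot(length(vois) == length(means))
  do.call(rbind, lapply(seq_along(vois), function(i) {
    v <- vois[[i]]; m <- means[[i]]
    data.frame(vertebra = v$vertebra, z0 = min(v$slice_range),
               n_slices = length(v$slice_range),
               center_row = unname(v$center["row"]),
               center_col = unname(v$center["col"]),
               semi_short = v$semi_short, semi_long = v$semi_long,
               n_voxels = m$n_voxels, mean_hu = m$mean_hu)
  }))
}
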