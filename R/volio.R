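#' CT volume and mask containers
#'
#' A `ct_volume` holds a 3D grid of CT numbers in Hounsfield units (HU),
#' indexed `[slice z, row y, col x]` with slice 1 the most superior, together
#' with the voxel spacing in mm. A `class_mask` is a voxel-aligned integer
#' labeling with the semantic classes used by the segmentation network
#' (0 = background, 1 = T1--T6, 2 = T7--T12, 3 = L1--L2). An `instance_mask`
#' labels individual vertebrae with positive integer ids and carries an
#' id-to-name mapping.
#'
#' @param voxels 3D numeric array of CT numbers, indexed `[z, y, x]`.
#' @param spacing numeric(3), voxel spacing in mm as `(z, y, x)`; all > 0.
#' @param labels 3D integer array aligned to a volume.
#' @param mapping named integer vector: values are instance ids present in
#'   `labels`, names are vertebra names (`"T1"`..`"T12"`, `"L1"`, `"L2"`, or
#'   `NA` for flagged/unnamed instances).
#' @return An object of class `ct_volume`, `class_mask` or `instance_mask`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L)
    stop("ct_volume: `voxels` must be a 3D array, got ",
         length(dim(voxels)), " dims", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: `spacing` must be three positive finite numbers (z, y, x)",
         call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("ct_volume: all voxel values must be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @rdname ct_volume
#' @export
class_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L)
    stop("class_mask: `labels` must be a 3D array", call. = FALSE)
  check_integerish(labels, "class_mask")
  bad <- setdiff(unique(as.integer(labels)), 0:3)
  if (length(bad))
    stop("class_mask: labels outside the class domain {0,1,2,3}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "class_mask")
}

#' @rdname ct_volume
#' @export
instance_mask <- function(labels, mapping, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L)
    stop("instance_mask: `labels` must be a 3D array", call. = FALSE)
  check_integerish(labels, "instance_mask")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  if (!setequal(ids, as.integer(mapping)))
    stop("instance_mask: mapping ids must be exactly the nonzero labels present",
         call. = FALSE)
  structure(list(labels = labels, mapping = mapping,
                 spacing = as.numeric(spacing)),
            class = "instance_mask")
}

check_integerish <- function(x, where) {
  if (any(!is.finite(x)) || any(x != round(x)))
    stop(where, ": labels must be integer-valued", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Vertebra names and their anatomical order
#'
#' The vertebral levels covered by a chest CT field of view, superior to
#' inferior: T1..T12 then L1, L2. `vertebra_order()` returns the rank of a
#' name in that order (T1 = 1, ..., L2 = 14).
#'
#' @param name character vector of vertebra names.
#' @return `vertebra_levels()`: character vector of the 14 names in order;
#'   `vertebra_order()`: integer ranks (NA for unknown names).
#' @examples
#' vertebra_order("L1") > vertebra_order("T12")
#' @export
vertebra_levels <- function() c(paste0("T", 1:12), "L1", "L2")

#' @rdname vertebra_levels
#' @export
vertebra_order <- function(name) match(name, vertebra_levels())

#' Semantic class of a vertebra name
#'
#' The segmentation task groups vertebrae into three classes:
#' 1 = T1--T6, 2 = T7--T12, 3 = L1--L2.
#'
#' @param name character vector of vertebra names.
#' @return integer class ids in `{1, 2, 3}`.
#' @export
vertebra_class <- function(name) {
  ord <- vertebra_order(name)
  ifelse(ord <= 6, 1L, ifelse(ord <= 12, 2L, 3L))
}

# --- NIfTI I/O ---------------------------------------------------------------
#
# Internal arrays are [z, y, x] with slice 1 the most superior. NIfTI stores
# [x, y, z] with +z superior (RAS-like), so writing permutes axes and reverses
# z; reading inverts that exactly, making round trips bit-identical. Files
# carrying orientation metadata are reoriented to RAS on read so that the
# superior->inferior slice convention (which the labeling rules rely on) holds
# regardless of how the file was stored.

#' Read and write volumes and masks as NIfTI
#'
#' Volumes are written with their HU values untouched; masks are written with
#' an integer datatype. On read, images carrying orientation metadata are
#' reoriented to the canonical RAS frame before being converted to the
#' package's `[z, y, x]`, superior-first indexing, so that "top down" /
#' "bottom up" naming rules are well defined. `read_mask()` validates the
#' label domain: a class mask may only contain values 0..3.
#'
#' @param v a [ct_volume].
#' @param m a [class_mask] or [instance_mask].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param type `"class"` or `"instance"`; how to validate and wrap the labels.
#' @param mapping for `type = "instance"`, the id-to-name mapping (see
#'   [instance_mask]); defaults to unnamed ids.
#' @return `read_volume()` a [ct_volume]; `read_mask()` a mask object; the
#'   writers return `path` invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  nii_write(v$voxels, v$spacing, path, datatype = "double")
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- nii_read(path)
  ct_volume(r$arr, r$spacing)
}

#' @rdname write_volume
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "class_mask") || inherits(m, "instance_mask"))
  nii_write(m$labels, m$spacing, path, datatype = "int32")
}

#' @rdname write_volume
#' @export
read_mask <- function(path, type = c("class", "instance"), mapping = NULL) {
  type <- match.arg(type)
  r <- nii_read(path)
  if (any(r$arr != round(r$arr)))
    stop("read_mask: file contains non-integer values: ", path, call. = FALSE)
  storage.mode(r$arr) <- "integer"
  if (type == "class") return(class_mask(r$arr, r$spacing))
  if (is.null(mapping)) {
    ids <- sort(unique(as.integer(r$arr)))
    ids <- ids[ids != 0L]
    mapping <- setNames(ids, rep(NA_character_, length(ids)))
  }
  instance_mask(r$arr, mapping, r$spacing)
}

nii_write <- function(arr, spacing, path, datatype) {
  if (!dir.exists(dirname(path)))
    stop("nii_write: directory does not exist: ", dirname(path), call. = FALSE)
  d <- dim(arr)
  # [z,y,x] superior-first  ->  [x,y,z] with z increasing toward superior
  out <- aperm(arr[d[1]:1, , , drop = FALSE], c(3, 2, 1))
  img <- RNifti::asNifti(out)
  RNifti::pixdim(img) <- spacing[c(3, 2, 1)]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

nii_read <- function(path) {
  if (!file.exists(path))
    stop("nii_read: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("nii_read: expected 3D data, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  ornt <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ornt) && !is.na(ornt) && nzchar(ornt) && ornt != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.numeric(pd[1:3]))[c(3, 2, 1)]
  arr <- aperm(as.array(img), c(3, 2, 1))
  d <- dim(arr)
  list(arr = arr[d[1]:1, , , drop = FALSE], spacing = spacing)
}
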