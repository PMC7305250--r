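#' Specification of a synthetic LDCT-like phantom
#'
#' Describes a thorax-like CT volume containing a column of non-touching
#' vertebra-like bodies: each vertebra is an elliptical cylinder with a
#' trabecular core of configurable mean HU wrapped in a denser cortical
#' shell, embedded in a soft-tissue "body" ellipse surrounded by air, with
#' optional additive Gaussian noise. The gap between vertebrae is required to
#' be positive because the anatomical-naming stage relies on vertebrae being
#' separable by connected-component labeling.
#'
#' Defaults emulate the scanning conditions the pipeline targets: 1-mm slice
#' thickness, 2-mm in-plane pixels (the network's working resolution), adult
#' vertebral-body dimensions, cortical thickness 0.8 mm (within the reported
#' anatomical 0.45--1.02 mm range), and trabecular attenuations spanning
#' normal to low bone mass.
#'
#' @param n_thoracic number of thoracic vertebrae (counted upward from T12;
#'   at most 12).
#' @param n_lumbar number of lumbar vertebrae (L1, L2; at most 2).
#' @param vb_height_mm,vb_gap_mm vertebral-body height and inter-body gap
#'   along z, mm; the gap must be positive.
#' @param vb_radius_row_mm,vb_radius_col_mm in-plane semi-axes of the body
#'   cross-section, mm (row = anterior--posterior, col = left--right).
#' @param trabecular_hu numeric vector of per-vertebra mean trabecular CT
#'   numbers (HU), superior to inferior; length `n_thoracic + n_lumbar`.
#'   Default: an even gradient from 180 down to 130 HU.
#' @param cortical_hu CT number of the cortical shell; must exceed every
#'   trabecular value.
#' @param background_hu CT number of the soft-tissue body; air outside the
#'   body is -1000 HU.
#' @param cortical_thickness_mm shell thickness, mm.
#' @param noise_sd standard deviation of additive Gaussian noise, HU (>= 0).
#' @param spacing voxel spacing `(z, y, x)` in mm; default `c(1, 2, 2)`.
#' @param volume_shape integer(3) `(slices, rows, cols)`; default sized to
#'   fit the column with an 8-slice margin on a 96 x 96 grid.
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [truth_bmd()]
#' @examples
#' spec <- phantom_spec(n_thoracic = 2, n_lumbar = 2, noise_sd = 0)
#' spec$names
#' @export
phantom_spec <- function(n_thoracic = 12, n_lumbar = 2,
                         vb_height_mm = 20, vb_gap_mm = 4,
                         vb_radius_row_mm = 15, vb_radius_col_mm = 18,
                         trabecular_hu = NULL,
                         cortical_hu = 400, background_hu = 30,
                         cortical_thickness_mm = 0.8,
                         noise_sd = 15,
                         spacing = c(1, 2, 2),
                         volume_shape = NULL,
                         seed = 1L) {
  n_thoracic <- as.integer(n_thoracic); n_lumbar <- as.integer(n_lumbar)
  if (n_thoracic < 0 || n_thoracic > 12) stop("phantom_spec: n_thoracic must be in 0..12")
  if (n_lumbar < 0 || n_lumbar > 2) stop("phantom_spec: n_lumbar must be in 0..2")
  n <- n_thoracic + n_lumbar
  if (n < 1) stop("phantom_spec: at least one vertebra required")
  if (vb_gap_mm <= 0)
    stop("phantom_spec: vb_gap_mm must be > 0 (vertebrae must not touch)")
  if (vb_height_mm <= 0 || vb_radius_row_mm <= 0 || vb_radius_col_mm <= 0)
    stop("phantom_spec: lengths must be positive")
  if (is.null(trabecular_hu))
    trabecular_hu <- round(seq(180, 130, length.out = n), 1)
  if (length(trabecular_hu) != n)
    stop("phantom_spec: trabecular_hu must have length n_thoracic + n_lumbar = ", n)
  if (cortical_hu <= max(trabecular_hu))
    stop("phantom_spec: cortical_hu must exceed max(trabecular_hu)")
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("phantom_spec: spacing must be three positive values (z, y, x)")
  if (is.null(volume_shape)) {
    column_mm <- n * vb_height_mm + (n - 1) * vb_gap_mm
    volume_shape <- c(ceiling(column_mm / spacing[1]) + 16L, 96L, 96L)
  }
  volume_shape <- as.integer(volume_shape)
  names_sup_inf <- c(if (n_thoracic > 0) paste0("T", seq(13 - n_thoracic, 12)),
                     if (n_lumbar > 0) paste0("L", seq_len(n_lumbar)))
  structure(list(
    n_thoracic = n_thoracic, n_lumbar = n_lumbar,
    vb_height_mm = vb_height_mm, vb_gap_mm = vb_gap_mm,
    vb_radius_row_mm = vb_radius_row_mm, vb_radius_col_mm = vb_radius_col_mm,
    trabecular_hu = as.numeric(trabecular_hu),
    cortical_hu = cortical_hu, background_hu = background_hu,
    cortical_thickness_mm = cortical_thickness_mm,
    noise_sd = noise_sd, spacing = spacing,
    volume_shape = volume_shape, seed = as.integer(seed),
    names = names_sup_inf
  ), class = "phantom_spec")
}

#' Ground-truth HU-to-BMD mapping of a phantom
#'
#' The phantom's true BMD per vertebra is defined through a stated
#' ground-truth linear calibration applied to its design trabecular HU:
#' `bmd = slope * hu + intercept`. The default truth calibration (slope 0.8
#' mg/cm^3 per HU, intercept 0) is an arbitrary documented constant chosen so
#' that truth and measured BMD are commensurable.
#'
#' @param spec a [phantom_spec].
#' @param truth_calibration a [calibration_model] with positive slope.
#' @return named numeric vector of per-vertebra true BMD, mg/cm^3.
#' @examples
#' truth_bmd(phantom_spec(n_thoracic = 1, n_lumbar = 2),
#'           calibration_model(1, 0))
#' @export
truth_bmd <- function(spec, truth_calibration = calibration_model(0.8, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (truth_calibration$slope <= 0)
    stop("truth_bmd: truth calibration slope must be > 0")
  setNames(truth_calibration$slope * spec$trabecular_hu +
             truth_calibration$intercept, spec$names)
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Builds the CT volume described by a [phantom_spec] together with its
#' ground-truth semantic class mask (1 = T1--T6, 2 = T7--T12, 3 = L1--L2),
#' named instance truth, and per-vertebra true mean HU and true BMD. The
#' vertebral column is centered in the volume; each vertebra occupies an
#' elliptical cylinder whose outer rim (in-plane and along z) of
#' `cortical_thickness_mm` is cortical and whose interior is trabecular.
#' Noise is independent additive Gaussian per voxel. Identical specs
#' (including `seed`) produce bit-identical samples.
#'
#' @param spec a [phantom_spec].
#' @param truth_calibration the ground-truth [calibration_model] used to
#'   define per-vertebra true BMD.
#' @return An object of class `phantom_sample`: a list with `volume`
#'   ([ct_volume]), `class_mask` ([class_mask]), `instance_mask`
#'   ([instance_mask]), `instance_truth` (list of `name`, `class_id`,
#'   `voxels` = linear voxel indices, `core_voxels`), `true_mean_hu`,
#'   `true_bmd`, `truth_calibration` and `spec`.
#' @examples
#' s <- generate_phantom(phantom_spec(n_thoracic = 1, n_lumbar = 2,
#'                                    noise_sd = 0, volume_shape = c(80, 48, 48)))
#' length(s$instance_truth)
#' @export
generate_phantom <- function(spec, truth_calibration = calibration_model(0.8, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$volume_shape
  sp <- spec$spacing
  n <- spec$n_thoracic + spec$n_lumbar
  column_mm <- n * spec$vb_height_mm + (n - 1) * spec$vb_gap_mm
  if (column_mm > d[1] * sp[1])
    stop(sprintf(paste0("generate_phantom: vertebral column (%.0f mm) does not fit",
                        " along slices (%.0f mm); enlarge volume_shape[1]"),
                 column_mm, d[1] * sp[1]))
  if (2 * spec$vb_radius_row_mm >= d[2] * sp[2])
    stop("generate_phantom: vertebra does not fit along rows; enlarge volume_shape[2]")
  if (2 * spec$vb_radius_col_mm >= d[3] * sp[3])
    stop("generate_phantom: vertebra does not fit along cols; enlarge volume_shape[3]")

  # voxel-center coordinates in mm
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  cy <- d[2] * sp[2] / 2
  cx <- d[3] * sp[3] / 2

  a <- spec$vb_radius_row_mm      # semi-axis along rows (y)
  b <- spec$vb_radius_col_mm      # semi-axis along cols (x)
  th <- spec$cortical_thickness_mm

  # in-plane membership, shared by all vertebrae (the column is straight)
  e2 <- function(sa, sb) outer(((yc - cy) / sa)^2, ((xc - cx) / sb)^2, `+`)
  outer_pl <- e2(a, b) <= 1
  core_pl <- e2(a - th, b - th) <= 1

  # soft-tissue body ellipse on air
  body_a <- min(2.2 * a, cy - sp[2])
  body_b <- min(2.2 * b, cx - sp[3])
  body_pl <- e2(body_a, body_b) <= 1

  # body plane replicated along z: air outside, soft tissue inside
  arr <- array(rep(ifelse(body_pl, spec$background_hu, -1000), each = d[1]),
               dim = d)

  cls <- array(0L, dim = d)
  inst <- array(0L, dim = d)
  z0_mm <- (d[1] * sp[1] - column_mm) / 2
  classes <- vertebra_class(spec$names)
  instance_truth <- vector("list", n)
  plane_n <- d[2] * d[3]
  outer_idx <- which(outer_pl)   # in-plane linear indices
  core_idx <- which(core_pl)

  for (i in seq_len(n)) {
    vz0 <- z0_mm + (i - 1) * (spec$vb_height_mm + spec$vb_gap_mm)
    vz1 <- vz0 + spec$vb_height_mm
    zs <- which(zc >= vz0 & zc < vz1)           # slices of this vertebra
    zs_core <- which(zc >= vz0 + th & zc < vz1 - th)  # away from endplates
    if (!length(zs))
      stop("generate_phantom: vertebra ", spec$names[i],
           " has no slices; check vb_height_mm vs spacing[1]")
    # linear indices: v = z + nz*(plane_idx - 1), 1-based
    vox <- as.vector(outer(zs, (outer_idx - 1L) * d[1], `+`))
    core <- as.vector(outer(zs_core, (core_idx - 1L) * d[1], `+`))
    arr[vox] <- spec$cortical_hu
    arr[core] <- spec$trabecular_hu[i]
    cls[vox] <- classes[i]
    inst[vox] <- i
    instance_truth[[i]] <- list(name = spec$names[i], class_id = classes[i],
                                voxels = sort(vox), core_voxels = sort(core))
  }

  if (spec$noise_sd > 0) {
    arr <- with_seed(spec$seed,
                     arr + array(rnorm(prod(d), 0, spec$noise_sd), dim = d))
  }

  tb <- truth_bmd(spec, truth_calibration)
  structure(list(
    volume = ct_volume(arr, sp),
    class_mask = class_mask(cls, sp),
    instance_mask = instance_mask(inst, setNames(seq_len(n), spec$names), sp),
    instance_truth = instance_truth,
    true_mean_hu = setNames(spec$trabecular_hu, spec$names),
    true_bmd = tb,
    truth_calibration = truth_calibration,
    spec = spec
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d vertebrae (%s..%s), volume %s, noise_sd %.3g HU\n",
              length(x$instance_truth), x$spec$names[1],
              tail(x$spec$names, 1),
              paste(x$spec$volume_shape, collapse = "x"), x$spec$noise_sd))
  invisible(x)
}

#' Write a phantom sample and its ground truth to disk
#'
#' Writes the volume and both masks as NIfTI, the per-vertebra truth table as
#' tab-separated text (`truth.tsv`: vertebra, class, true HU, true BMD) and
#' the generating spec as a DCF config (`spec.dcf`).
#'
#' @param sample a `phantom_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(sample, dir) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(sample$volume, file.path(dir, "volume.nii.gz"))
  write_mask(sample$class_mask, file.path(dir, "class_mask.nii.gz"))
  write_mask(sample$instance_mask, file.path(dir, "instance_mask.nii.gz"))
  truth <- data.frame(vertebra = names(sample$true_bmd),
                      class = vertebra_class(names(sample$true_bmd)),
                      true_hu = as.numeric(sample$true_mean_hu),
                      true_bmd = as.numeric(sample$true_bmd))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_spec_config(sample$spec, file.path(dir, "spec.dcf"))
  invisible(dir)
}

#' Serialize / restore a phantom spec as a plain-text config
#'
#' @param spec a [phantom_spec].
#' @param path file path for the DCF (key: value) config.
#' @return `read_spec_config()` returns a [phantom_spec].
#' @export
write_spec_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  flat <- lapply(spec[setdiff(names(spec), "names")],
                 function(x) paste(x, collapse = " "))
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  m <- read.dcf(path)
  g <- function(key) strsplit(m[1, key], " ", fixed = TRUE)[[1]]
  phantom_spec(
    n_thoracic = as.integer(g("n_thoracic")),
    n_lumbar = as.integer(g("n_lumbar")),
    vb_height_mm = as.numeric(g("vb_height_mm")),
    vb_gap_mm = as.numeric(g("vb_gap_mm")),
    vb_radius_row_mm = as.numeric(g("vb_radius_row_mm")),
    vb_radius_col_mm = as.numeric(g("vb_radius_col_mm")),
    trabecular_hu = as.numeric(g("trabecular_hu")),
    cortical_hu = as.numeric(g("cortical_hu")),
    background_hu = as.numeric(g("background_hu")),
    cortical_thickness_mm = as.numeric(g("cortical_thickness_mm")),
    noise_sd = as.numeric(g("noise_sd")),
    spacing = as.numeric(g("spacing")),
    volume_shape = as.integer(g("volume_shape")),
    seed = as.integer(g("seed")))
}
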