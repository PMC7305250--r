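#' Measure the target vertebrae on a labeled volume
#'
#' For each named target vertebra present among the instances, places the
#' cylindrical elliptical VOI ([instance_voi()]) and computes the mean CT
#' number ([mean_ct()]).
#'
#' @param v a [ct_volume] (same grid as the instances).
#' @param instances named `vertebra_instance` list (see [label_vertebrae()]).
#' @param targets vertebra names to measure (default T12, L1, L2).
#' @param voi_height_mm VOI cylinder height, mm.
#' @return list with `measurements` (data frame vertebra, mean_hu,
#'   n_voxels), `vois` and `flags`.
#' @export
measure_targets <- function(v, instances, targets = c("T12", "L1", "L2"),
                            voi_height_mm = 9) {
  stopifnot(inherits(v, "ct_volume"))
  d <- dim(v$voxels)
  names_ <- vapply(instances, function(i) i$name %||% NA_character_, "")
  rows <- list(); vois <- list(); flags <- character()
  for (tg in targets) {
    i <- match(tg, names_)
    if (is.na(i)) { flags <- c(flags, paste0("missing_", tg)); next }
    voi <- instance_voi(instances[[i]], d, v$spacing, voi_height_mm)
    mc <- mean_ct(v, voi)
    vois[[tg]] <- voi
    rows[[tg]] <- data.frame(vertebra = tg, mean_hu = mc$mean_hu,
                             n_voxels = mc$n_voxels)
  }
  if (!length(rows))
    stop("measure_targets: none of the target vertebrae could be measured",
         call. = FALSE)
  list(measurements = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       vois = vois, flags = flags)
}

#' Run the full measurement pipeline on one volume
#'
#' Chains segmentation (network inference, or a supplied oracle/ground-truth
#' class mask), anatomical labeling, VOI measurement of T12/L1/L2, linear
#' calibration and bone-mass classification into a single [make_report()]
#' result.
#'
#' @param v a [ct_volume], already at the working resolution (see
#'   [rescale_axial()] / [crop_centered()] for preprocessing).
#' @param calibration a [calibration_model].
#' @param net a trained `dense_unet` (ignored when `oracle_mask` is given).
#' @param oracle_mask optional [class_mask] to use instead of network
#'   inference (tests the deterministic half of the pipeline).
#' @param depth,stride_z sliding-window inference parameters.
#' @param min_voxels speckle threshold for instance extraction.
#' @return list with `report` ([make_report()]), `instances`,
#'   `instance_mask`, `class_mask`, `measurements`, `warnings`.
#' @export
run_pipeline <- function(v, calibration, net = NULL, oracle_mask = NULL,
                         depth = 64, stride_z = 32, min_voxels = 100) {
  stopifnot(inherits(v, "ct_volume"), inherits(calibration, "calibration_model"))
  cm <- if (!is.null(oracle_mask)) {
    stopifnot(inherits(oracle_mask, "class_mask"))
    oracle_mask
  } else {
    if (is.null(net)) stop("run_pipeline: need a network or an oracle mask")
    predict_volume(net, v, depth = depth, stride_z = stride_z)
  }
  lab <- label_vertebrae(cm, min_voxels = min_voxels)
  meas <- measure_targets(v, lab$instances)
  report <- make_report(meas$measurements, calibration)
  report$flags <- unique(c(report$flags, meas$flags))
  list(report = report, instances = lab$instances,
       instance_mask = lab$instance_mask, class_mask = cm,
       measurements = meas$measurements,
       warnings = c(lab$warnings %||% character(), meas$flags))
}
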