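#' Classify bone mass from volumetric BMD
#'
#' QCT bone-mass categories: normal (> 120 mg/cm^3), osteopenia
#' (80--120 mg/cm^3, endpoints included), osteoporosis (< 80 mg/cm^3).
#' Negative BMD values are still classified but flagged implausible via the
#' `"implausible"` attribute.
#'
#' @param bmd numeric vector of BMD values, mg/cm^3 (finite).
#' @return factor with levels `normal`, `osteopenia`, `osteoporosis`;
#'   attribute `implausible` is a logical vector marking negative inputs.
#' @examples
#' classify_bone_mass(c(121, 120, 80, 79.9))
#' @export
classify_bone_mass <- function(bmd) {
  if (any(!is.finite(bmd)))
    stop("classify_bone_mass: BMD must be finite", call. = FALSE)
  cat_ <- ifelse(bmd > 120, "normal",
                 ifelse(bmd >= 80, "osteopenia", "osteoporosis"))
  out <- factor(cat_, levels = c("normal", "osteopenia", "osteoporosis"))
  attr(out, "implausible") <- bmd < 0
  out
}

#' Binary low-bone-mass indicator
#'
#' "Low BMD" pools osteopenia and osteoporosis, the screening-relevant
#' complement of normal bone mass.
#'
#' @param category factor/character of bone-mass categories.
#' @return logical vector: `TRUE` for osteopenia or osteoporosis.
#' @export
is_low_bmd <- function(category) as.character(category) != "normal"

#' Assemble the clinical BMD report
#'
#' Applies the calibration to the per-vertebra mean CT numbers of the target
#' vertebrae (T12, L1, L2) and derives the standard reportable metric: the
#' L1--L2 BMD average, with its bone-mass category. T12 BMD is carried as a
#' reference value; when either lumbar vertebra is missing no category is
#' assigned and the report is flagged `t12_reference_only`.
#'
#' @param measurements data frame with columns `vertebra` (among
#'   `"T12", "L1", "L2"`) and `mean_hu`; optionally `n_voxels`.
#' @param model a [calibration_model].
#' @return An object of class `bmd_report`: `per_vertebra` data frame
#'   (vertebra, mean_hu, bmd), `l1l2_average`, `t12_reference`, `category`
#'   (or `NA`), and `flags` (stable codes).
#' @examples
#' m <- calibration_model(1, 0)
#' r <- make_report(data.frame(vertebra = c("L1", "L2"), mean_hu = c(100, 110)), m)
#' r$l1l2_average  # 105, osteopenia
#' @export
make_report <- function(measurements, model) {
  stopifnot(is.data.frame(measurements), inherits(model, "calibration_model"))
  meas <- measurements[measurements$vertebra %in% c("T12", "L1", "L2"), , drop = FALSE]
  if (nrow(meas) == 0)
    stop("make_report: no target vertebra (T12/L1/L2) measured", call. = FALSE)
  meas <- meas[order(vertebra_order(meas$vertebra)), , drop = FALSE]
  meas$bmd <- apply_calibration(model, meas$mean_hu)
  flags <- character()
  bmd_of <- function(v) if (v %in% meas$vertebra) meas$bmd[meas$vertebra == v] else NA_real_
  t12 <- bmd_of("T12"); l1 <- bmd_of("L1"); l2 <- bmd_of("L2")
  if (!is.na(l1) && !is.na(l2)) {
    l1l2 <- (l1 + l2) / 2
    category <- classify_bone_mass(l1l2)
    if (attr(category, "implausible")[1]) flags <- c(flags, "implausible_bmd")
    category <- as.character(category)
  } else {
    l1l2 <- NA_real_
    category <- NA_character_
    flags <- c(flags, "missing_lumbar", if (!is.na(t12)) "t12_reference_only")
  }
  missing_targets <- setdiff(c("T12", "L1", "L2"), meas$vertebra)
  if (length(missing_targets))
    flags <- c(flags, paste0("missing_", missing_targets))
  structure(list(per_vertebra = meas[, c("vertebra", "mean_hu", "bmd")],
                 l1l2_average = l1l2,
                 t12_reference = t12,
                 category = category,
                 flags = unique(flags)),
            class = "bmd_report")
}

#' @export
print.bmd_report <- function(x, ...) {
  cat("<bmd_report>\n")
  pv <- x$per_vertebra
  for (i in seq_len(nrow(pv)))
    cat(sprintf("  %-3s  mean CT %7.1f HU   BMD %7.1f mg/cm3\n",
                pv$vertebra[i], pv$mean_hu[i], pv$bmd[i]))
  if (!is.na(x$l1l2_average))
    cat(sprintf("  L1-L2 average: %.1f mg/cm3  ->  %s\n",
                x$l1l2_average, x$category))
  if (!is.na(x$t12_reference))
    cat(sprintf("  T12 reference: %.1f mg/cm3\n", x$t12_reference))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a BMD report as a delimited table
#'
#' @param report a `bmd_report`.
#' @param path output path for the tab-separated table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bmd_report"))
  pv <- report$per_vertebra
  summary_rows <- data.frame(
    vertebra = c("L1-L2_avg", "T12_ref", "category", "flags"),
    mean_hu = NA_real_,
    bmd = c(report$l1l2_average, report$t12_reference, NA, NA),
    note = c("", "", ifelse(is.na(report$category), "", report$category),
             paste(report$flags, collapse = ";")))
  pv$note <- ""
  write.table(rbind(pv, summary_rows), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
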