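#' Linear HU-to-BMD calibration model
#'
#' BMD is obtained from the mean trabecular CT number by a first-degree
#' linear function `bmd = slope * hu + intercept` (mg/cm^3). The model is
#' either fitted by ordinary least squares from paired (mean HU, reference
#' BMD) data ([fit_bmd_calibration]) or supplied externally from quality
#' assurance phantom scanning ([set_external_calibration]).
#'
#' @param slope mg/cm^3 per HU; must be positive and finite.
#' @param intercept mg/cm^3.
#' @param n_pairs number of pairs the model was fitted on (0 if external).
#' @param fit_r2 coefficient of determination of the fit, or `NULL`.
#' @param provenance free-text origin tag (`"fitted"`, `"external"`, ...).
#' @return An object of class `calibration_model`.
#' @examples
#' m <- calibration_model(0.8, 5)
#' apply_calibration(m, 100)  # 85
#' @export
calibration_model <- function(slope, intercept, n_pairs = 0L, fit_r2 = NULL,
                              provenance = "external") {
  if (!is.finite(slope) || slope <= 0)
    stop("calibration_model: slope must be positive and finite, got ", slope,
         call. = FALSE)
  if (!is.finite(intercept))
    stop("calibration_model: intercept must be finite", call. = FALSE)
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 n_pairs = as.integer(n_pairs), fit_r2 = fit_r2,
                 provenance = provenance),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> BMD = %.6g * HU + %.6g  [%s%s%s]\n",
              x$slope, x$intercept, x$provenance,
              if (x$n_pairs > 0) sprintf(", n = %d", x$n_pairs) else "",
              if (!is.null(x$fit_r2)) sprintf(", R2 = %.4f", x$fit_r2) else ""))
  invisible(x)
}

#' Fit the linear calibration from paired HU / BMD data
#'
#' Ordinary least squares of reference BMD on mean CT number, pooled over
#' target vertebrae (the standard usage; a per-level fit can be obtained by
#' subsetting the pairs before calling).
#'
#' @param hu numeric vector of mean trabecular CT numbers (HU), or a
#'   two-column data frame `(hu, bmd)`.
#' @param bmd numeric vector of reference BMD values (mg/cm^3).
#' @return A fitted [calibration_model] with `fit_r2` and `n_pairs` set.
#' @examples
#' fit_bmd_calibration(c(0, 100, 200), c(5, 85, 165))  # slope 0.8, intercept 5
#' @export
fit_bmd_calibration <- function(hu, bmd = NULL) {
  if (is.data.frame(hu)) { bmd <- hu[[2]]; hu <- hu[[1]] }
  keep <- is.finite(hu) & is.finite(bmd)
  hu <- hu[keep]; bmd <- bmd[keep]
  if (length(hu) < 2)
    stop("fit_bmd_calibration: need at least 2 pairs", call. = FALSE)
  if (sd(hu) == 0)
    stop("fit_bmd_calibration: HU values are constant; slope is unidentifiable",
         call. = FALSE)
  fit <- lm(bmd ~ hu)
  r2 <- 1 - sum(fit$residuals^2) / sum((bmd - mean(bmd))^2)
  calibration_model(coef(fit)[["hu"]], coef(fit)[["(Intercept)"]],
                    n_pairs = length(hu), fit_r2 = r2, provenance = "fitted")
}

#' Apply a calibration model to mean CT numbers
#'
#' @param model a [calibration_model].
#' @param mean_hu numeric vector of mean CT numbers (HU).
#' @return BMD values, mg/cm^3.
#' @export
apply_calibration <- function(model, mean_hu) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * mean_hu + model$intercept
}

#' @rdname calibration_model
#' @export
set_external_calibration <- function(slope, intercept) {
  calibration_model(slope, intercept, n_pairs = 0L, provenance = "external")
}

#' Store / load a calibration model as structured text
#'
#' DCF (key: value) file with slope, intercept, provenance and date, so a
#' QA-phantom-derived calibration can be carried between runs.
#'
#' @param model a [calibration_model].
#' @param path file path.
#' @return `read_calibration()` returns a [calibration_model].
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  df <- data.frame(slope = format(model$slope, digits = 17),
                   intercept = format(model$intercept, digits = 17),
                   n_pairs = model$n_pairs,
                   fit_r2 = if (is.null(model$fit_r2)) NA else model$fit_r2,
                   provenance = model$provenance,
                   date = format(Sys.Date()))
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- read.dcf(path)
  r2 <- suppressWarnings(as.numeric(m[1, "fit_r2"]))
  calibration_model(as.numeric(m[1, "slope"]), as.numeric(m[1, "intercept"]),
                    n_pairs = as.integer(m[1, "n_pairs"]),
                    fit_r2 = if (is.na(r2)) NULL else unname(r2),
                    provenance = unname(m[1, "provenance"]))
}
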