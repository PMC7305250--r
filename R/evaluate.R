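#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two voxel sets (given as index
#' vectors or logical arrays over a common grid). Two empty sets are defined
#' to have Dice 1, flagged via attribute `both_empty`.
#'
#' @param a,b integer index vectors or logical arrays.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice_coefficient(1:100, 51:150)  # 0.5
#' @export
dice_coefficient <- function(a, b) {
  if (is.logical(a) || is.array(a)) a <- which(a != 0)
  if (is.logical(b) || is.array(b)) b <- which(b != 0)
  if (!length(a) && !length(b))
    return(structure(1, both_empty = TRUE))
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Match predicted instances to truth and score labeling accuracy
#'
#' Each truth instance is matched to the predicted instance with maximal
#' voxel overlap; the match is correct when the assigned names agree. An
#' unmatched truth instance counts as incorrect. Results are reported per
#' vertebral level and overall.
#'
#' @param pred list of predicted `vertebra_instance`s (named).
#' @param truth list of truth instances (`name`, `voxels`).
#' @return list with `per_level` data frame (level, n, n_correct, accuracy),
#'   `overall` accuracy, and `matches` (per-truth matched prediction name).
#' @export
labeling_accuracy <- function(pred, truth) {
  if (!length(truth)) stop("labeling_accuracy: empty truth", call. = FALSE)
  matched <- vapply(truth, function(tr) {
    if (!length(pred)) return(NA_character_)
    ov <- vapply(pred, function(pi) length(intersect(pi$voxels, tr$voxels)), 0)
    if (max(ov) == 0) return(NA_character_)
    nm <- pred[[which.max(ov)]]$name
    if (is.null(nm)) NA_character_ else nm
  }, "")
  truth_names <- vapply(truth, `[[`, "", "name")
  correct <- !is.na(matched) & matched == truth_names
  per_level <- data.frame(level = truth_names,
                          n = 1L,
                          n_correct = as.integer(correct),
                          accuracy = as.numeric(correct))
  list(per_level = per_level, overall = mean(correct),
       matches = setNames(matched, truth_names))
}

#' Aggregate labeling accuracy across scans
#'
#' Per-scan accounting (the default interpretation of per-level accuracy
#' tables): each scan contributes one correct/incorrect outcome per level it
#' contains.
#'
#' @param results list of [labeling_accuracy()] results, one per scan.
#' @return data frame (level, n, n_correct, accuracy) plus an `"overall"` row.
#' @export
aggregate_labeling_accuracy <- function(results) {
  all_levels <- do.call(rbind, lapply(results, `[[`, "per_level"))
  agg <- do.call(rbind, lapply(split(all_levels, all_levels$level), function(d)
    data.frame(level = d$level[1], n = sum(d$n), n_correct = sum(d$n_correct),
               accuracy = sum(d$n_correct) / sum(d$n))))
  agg <- agg[order(vertebra_order(agg$level)), ]
  overall <- data.frame(level = "overall", n = sum(agg$n),
                        n_correct = sum(agg$n_correct),
                        accuracy = sum(agg$n_correct) / sum(agg$n))
  rownames(agg) <- NULL
  rbind(agg, overall)
}

#' Linear-regression and Bland-Altman agreement statistics
#'
#' OLS of predicted on reference BMD (slope, intercept, R^2) together with
#' the Bland-Altman summary of the paired differences `pred - ref`: mean
#' difference and the 95% limits of agreement `mean +/- 1.96 * sd` (sd with
#' the n-1 denominator).
#'
#' @param pred,ref paired numeric vectors (n >= 3).
#' @return object of class `agreement_stats`: slope, intercept, r2,
#'   mean_diff, sd_diff, loa_low, loa_high, n.
#' @export
bmd_agreement <- function(pred, ref) {
  keep <- is.finite(pred) & is.finite(ref)
  pred <- pred[keep]; ref <- ref[keep]
  if (length(pred) < 3)
    stop("bmd_agreement: need at least 3 pairs", call. = FALSE)
  if (sd(ref) == 0)
    stop("bmd_agreement: reference has zero variance", call. = FALSE)
  fit <- lm(pred ~ ref)
  diffs <- pred - ref
  md <- mean(diffs); sdd <- sd(diffs)
  r2 <- 1 - sum(fit$residuals^2) / sum((pred - mean(pred))^2)
  structure(list(slope = unname(coef(fit)["ref"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r2 = r2,
                 mean_diff = md, sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 n = length(pred)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n=%d  pred = %.3f*ref + %.2f (R2 %.4f)\n",
              x$n, x$slope, x$intercept, x$r2))
  cat(sprintf("  Bland-Altman: mean diff %.2f, 95%% LoA (%.2f, %.2f)\n",
              x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' ROC curve and AUC (Mann-Whitney)
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' higher than a random negative, ties counted 1/2. Curve points (FPR, TPR)
#' are produced at every threshold between distinct scores; the trapezoidal
#' area under that curve equals the Mann-Whitney value (an internal
#' cross-check used by the test suite).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1 or logical).
#' @return list with `auc` (Mann-Whitney), `auc_trapezoid`, and `curve`
#'   (data frame threshold, fpr, tpr).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("roc_auc: need both classes present", call. = FALSE)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  # Mann-Whitney via midranks
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  auc_trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, auc_trapezoid = auc_trap,
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Diagnostic 2x2 performance for osteoporosis / low-BMD detection
#'
#' Binarizes predicted and reference bone-mass categories per screening task
#' (`"osteoporosis"`: osteoporosis vs not; `"low_bmd"`: osteopenia or
#' osteoporosis vs normal), and reports sensitivity, specificity, PPV and
#' NPV with their raw counts. When continuous predicted BMD values are
#' supplied, the AUC against the reference binarization is computed with
#' score `-BMD` (lower BMD = more positive), optionally with a stratified
#' bootstrap 95% CI.
#'
#' @param pred_cat predicted categories (factor/character).
#' @param truth_cat reference categories.
#' @param task `"osteoporosis"` or `"low_bmd"`.
#' @param pred_bmd optional continuous predicted BMD for the ROC analysis.
#' @param ci_boot number of stratified bootstrap resamples for the AUC CI
#'   (0 = no CI).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `diagnostic_stats` with fields sensitivity,
#'   specificity, ppv, npv (each a list value/num/den), counts (tp, fp, tn,
#'   fn), auc, auc_ci.
#' @export
diagnostic_table <- function(pred_cat, truth_cat,
                             task = c("osteoporosis", "low_bmd"),
                             pred_bmd = NULL, ci_boot = 0, seed = 1) {
  task <- match.arg(task)
  binarize <- function(cat_) {
    if (task == "osteoporosis") as.character(cat_) == "osteoporosis"
    else is_low_bmd(cat_)
  }
  p <- binarize(pred_cat); t <- binarize(truth_cat)
  if (!any(t) || all(t))
    warning("diagnostic_table: a reference class is empty; ratios undefined",
            call. = FALSE)
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) list(value = if (den > 0) num / den else NA_real_,
                                   num = num, den = den)
  auc <- NULL; auc_ci <- NULL
  if (!is.null(pred_bmd)) {
    score <- -pred_bmd
    auc <- roc_auc(score, t)$auc
    if (ci_boot > 0) {
      ipos <- which(t); ineg <- which(!t)
      boots <- with_seed(seed, vapply(seq_len(ci_boot), function(b) {
        i <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
        roc_auc(score[i], t[i])$auc
      }, 0))
      auc_ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  structure(list(task = task,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 auc = auc, auc_ci = auc_ci),
            class = "diagnostic_stats")
}

#' @export
print.diagnostic_stats <- function(x, ...) {
  pc <- function(r) sprintf("%.2f%% (%d/%d)", 100 * r$value, r$num, r$den)
  cat(sprintf("<diagnostic_stats> task: %s\n", x$task))
  if (!is.null(x$auc))
    cat(sprintf("  AUC %.3f%s\n", x$auc,
                if (!is.null(x$auc_ci))
                  sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci[1], x$auc_ci[2])
                else ""))
  cat("  sensitivity", pc(x$sensitivity), " specificity", pc(x$specificity), "\n")
  cat("  PPV", pc(x$ppv), " NPV", pc(x$npv), "\n")
  invisible(x)
}

#' Per-level Dice between a predicted and a truth instance segmentation
#'
#' Dice is computed per vertebra instance (matching prediction to truth by
#' name) and averaged per level; the overall value is the mean of per-level
#' means.
#'
#' @param pred named list of predicted instances (`name`, `voxels`).
#' @param truth list of truth instances (`name`, `voxels`).
#' @return data frame (level, dice) with an `"overall"` row appended.
#' @export
per_level_dice <- function(pred, truth) {
  pnames <- vapply(pred, function(p) p$name %||% NA_character_, "")
  rows <- lapply(truth, function(tr) {
    i <- match(tr$name, pnames)
    d <- if (is.na(i)) 0 else dice_coefficient(pred[[i]]$voxels, tr$voxels)
    data.frame(level = tr$name, dice = as.numeric(d))
  })
  df <- do.call(rbind, rows)
  df <- df[order(vertebra_order(df$level)), ]
  rownames(df) <- NULL
  rbind(df, data.frame(level = "overall", dice = mean(df$dice)))
}
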