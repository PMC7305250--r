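test_that("Dice coefficient is exact, symmetric and bounded", {
  expect_equal(dice_coefficient(1:100, 1:100), 1)
  expect_equal(dice_coefficient(1:50, 51:100), 0)
  expect_equal(dice_coefficient(1:100, 51:150), 0.5)
  both <- dice_coefficient(integer(0), integer(0))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  set.seed(1)
  for (k in 1:10) {
    a <- sample(1000, 200); b <- sample(1000, 300)
    d <- dice_coefficient(a, b)
    expect_equal(d, dice_coefficient(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    # removing intersection voxels can only reduce overlap
    drop <- intersect(a, b)[1:10]
    expect_lte(dice_coefficient(setdiff(a, drop), b), d)
  }
})

test_that("labeling accuracy matches by maximal overlap, per level and overall", {
  truth <- list(list(name = "T12", voxels = 1:100),
                list(name = "L1", voxels = 201:300),
                list(name = "L2", voxels = 401:500))
  pred_ok <- lapply(truth, function(t) list(name = t$name, voxels = t$voxels))
  expect_equal(labeling_accuracy(pred_ok, truth)$overall, 1)

  # off-by-one shift of all names scores zero
  shifted <- list(list(name = "L1", voxels = 1:100),
                  list(name = "L2", voxels = 201:300),
                  list(name = "T12", voxels = 401:500))
  expect_equal(labeling_accuracy(shifted, truth)$overall, 0)

  # unmatched truth instance counts as incorrect
  missing <- pred_ok[1:2]
  expect_equal(labeling_accuracy(missing, truth)$overall, 2 / 3)
})

test_that("39 correct scans in 40 give 97.5% at every level", {
  truth <- lapply(vertebra_levels(), function(n)
    list(name = n, voxels = (vertebra_order(n) * 100):(vertebra_order(n) * 100 + 50)))
  good <- labeling_accuracy(truth, truth)
  bad_pred <- truth
  for (i in seq_along(bad_pred))                    # every level wrong once
    bad_pred[[i]]$name <- rev(vertebra_levels())[i]
  bad <- labeling_accuracy(bad_pred, truth)
  agg <- aggregate_labeling_accuracy(c(rep(list(good), 39), list(bad)))
  per_level <- agg[agg$level != "overall", ]
  expect_equal(nrow(per_level), 14)
  expect_true(all(per_level$accuracy == 0.975))
  expect_equal(agg$accuracy[agg$level == "overall"], 0.975)
})

test_that("agreement statistics match their closed forms", {
  ref <- c(80, 100, 120, 140, 160)
  a <- bmd_agreement(ref, ref)
  expect_equal(a$slope, 1); expect_equal(a$r2, 1)
  expect_equal(a$mean_diff, 0); expect_equal(a$loa_low, a$loa_high)

  b <- bmd_agreement(ref + 3, ref)
  expect_equal(b$mean_diff, 3)
  expect_equal(b$sd_diff, 0)
  expect_error(bmd_agreement(c(1, 2), c(1, 2)), "at least 3")
  expect_error(bmd_agreement(c(1, 2, 3), c(5, 5, 5)), "variance")
})

test_that("Bland-Altman recovers a simulated bias and limits of agreement", {
  set.seed(374)
  ref <- runif(374, 60, 160)
  pred <- ref + rnorm(374, 2, 6)
  a <- bmd_agreement(pred, ref)
  expect_lt(abs(a$mean_diff - 2), 3 * 6 / sqrt(374))
  expect_lt(abs(a$loa_low - (2 - 1.96 * 6)), 1.5)
  expect_lt(abs(a$loa_high - (2 + 1.96 * 6)), 1.5)
  # limits widen monotonically with noise
  wider <- bmd_agreement(ref + rnorm(374, 2, 12), ref)
  expect_gt(wider$loa_high - wider$loa_low, a$loa_high - a$loa_low)
})

test_that("AUC equals the Mann-Whitney pair probability", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  # ties count one half
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc, 0.875)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # null scores: AUC near 1/2 at large n
  set.seed(5)
  expect_lt(abs(roc_auc(rnorm(4000), rbinom(4000, 1, 0.4))$auc - 0.5), 0.05)
})

test_that("trapezoid area under the ROC curve equals Mann-Whitney to 1e-10", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(10:80, 1)
    scores <- sample(1:15, n, replace = TRUE) + rnorm(n, 0, 0.01)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(120)
  labels <- rbinom(120, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("diagnostic table reproduces published-style counts", {
  perfect <- diagnostic_table(rep(c("osteoporosis", "normal"), c(10, 20)),
                              rep(c("osteoporosis", "normal"), c(10, 20)),
                              task = "osteoporosis")
  expect_equal(perfect$sensitivity$value, 1)
  expect_equal(perfect$specificity$value, 1)
  expect_equal(perfect$ppv$value, 1)
  expect_equal(perfect$npv$value, 1)

  # counts TP=54, FN=9, TN=310, FP=1
  truth <- rep(c("osteoporosis", "normal"), c(63, 311))
  pred <- c(rep("osteoporosis", 54), rep("osteopenia", 9),
            rep("normal", 310), rep("osteoporosis", 1))
  d <- diagnostic_table(pred, truth, task = "osteoporosis")
  expect_equal(d$sensitivity$num, 54); expect_equal(d$sensitivity$den, 63)
  expect_equal(round(100 * d$sensitivity$value, 2), 85.71)
  expect_equal(d$specificity$num, 310); expect_equal(d$specificity$den, 311)
  expect_equal(round(100 * d$specificity$value, 2), 99.68)
})

test_that("ROC direction and low-BMD pooling behave as screening expects", {
  set.seed(3)
  truth_bmd_ <- c(runif(40, 40, 75), runif(60, 125, 180))
  truth_cat <- classify_bone_mass(truth_bmd_)
  pred_bmd <- truth_bmd_ + rnorm(100, 0, 5)
  pred_cat <- classify_bone_mass(pred_bmd)
  d <- diagnostic_table(pred_cat, truth_cat, task = "osteoporosis",
                        pred_bmd = pred_bmd, ci_boot = 200, seed = 4)
  expect_gt(d$auc, 0.95)                  # lower BMD scores more positive
  expect_length(d$auc_ci, 2)
  expect_lte(d$auc_ci[1], d$auc)

  dl <- diagnostic_table(pred_cat, truth_cat, task = "low_bmd")
  expect_equal(dl$counts[["tp"]] + dl$counts[["fn"]], 40)

  # random predictions sit near the null
  perm <- diagnostic_table(sample(as.character(pred_cat)), truth_cat,
                           task = "low_bmd")
  expect_lt(abs(perm$sensitivity$value - mean(is_low_bmd(pred_cat))), 0.25)
})

test_that("per-level Dice averages instances and then levels", {
  truth <- list(list(name = "L1", voxels = 1:100),
                list(name = "L2", voxels = 201:300))
  pred <- list(list(name = "L1", voxels = 1:100),
               list(name = "L2", voxels = 251:350))
  d <- per_level_dice(pred, truth)
  expect_equal(d$dice[d$level == "L1"], 1)
  expect_equal(d$dice[d$level == "L2"], 0.5)
  expect_equal(d$dice[d$level == "overall"], 0.75)
})
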