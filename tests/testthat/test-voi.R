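test_that("middle slice range follows the floor-midpoint rule", {
  expect_equal(middle_slices(list(z_extent = c(10, 30)), 9, 1), 16:24)
  expect_equal(middle_slices(list(z_extent = c(1, 9)), 9, 1), 1:9)
  expect_error(middle_slices(list(z_extent = c(1, 7), name = "L1"), 9, 1),
               "too thin")
  # 2-mm slices need only round(9/2) = 4 slices
  expect_length(middle_slices(list(z_extent = c(1, 9)), 9, 2), 4)
})

test_that("ellipse VOI on a disk honors the 30% area and 20% short-arm rules", {
  disk <- disk_region(50)
  v <- fit_ellipse_voi(disk, c(1, 1))
  W <- max(apply(disk, 1, function(r) {
    rl <- rle(r); if (!any(r)) 0L else max(rl$lengths[rl$values]) }))
  expect_equal(v$max_row_mm, W)
  expect_equal(v$semi_short, 0.20 * W)
  expect_equal(pi * v$semi_short * v$semi_long / v$area_mm2, 0.30,
               tolerance = 1e-12)
  expect_lt(max(abs(v$center - (2 * 50 + 21 + 1) / 2)), 0.5)  # centered
})

test_that("VOI identities hold on random convex regions and anisotropic pixels", {
  set.seed(21)
  for (k in 1:25) {
    a <- runif(1, 8, 30); b <- runif(1, 8, 30)
    sp <- c(runif(1, 0.5, 3), runif(1, 0.5, 3))
    reg <- outer(((seq_len(80) - 40.5) * sp[1] / a)^2,
                 ((seq_len(80) - 40.5) * sp[2] / b)^2, `+`) <= 1
    if (sum(reg) < 20) next
    v <- suppressWarnings(fit_ellipse_voi(reg, sp))
    expect_equal(pi * v$semi_short * v$semi_long / v$area_mm2, 0.30,
                 tolerance = 1e-12)
    # the short-arm rule holds whenever the inferred long axis is the longer
    if (!"axes_swapped" %in% v$warnings)
      expect_equal(v$semi_short / v$max_row_mm, 0.20, tolerance = 1e-12)
  }
})

test_that("degenerate geometry swaps axes with a warning", {
  flat <- matrix(FALSE, 40, 120)
  flat[19:22, 11:110] <- TRUE            # 4 x 100 ribbon: W dominates area
  w <- capture_warnings(v <- fit_ellipse_voi(flat, c(1, 1)))
  expect_match(w, "swap", all = FALSE)
  expect_lte(v$semi_short, v$semi_long)
  expect_true("axes_swapped" %in% v$warnings)
  expect_error(fit_ellipse_voi(matrix(FALSE, 5, 5), c(1, 1)), "empty")
})

test_that("phantom VOIs stay inside the trabecular core", {
  s <- generate_phantom(phantom_spec(n_thoracic = 2, n_lumbar = 2,
                                     noise_sd = 0, cortical_thickness_mm = 1.0,
                                     volume_shape = c(110, 48, 48)))
  lab <- label_vertebrae(s$class_mask)
  d <- dim(s$volume$voxels)
  for (tg in c("T12", "L1", "L2")) {
    i <- which(vapply(lab$instances, `[[`, "", "name") == tg)
    voi <- instance_voi(lab$instances[[i]], d, s$volume$spacing)
    # rasterize the ellipse and check membership in the core voxel set
    ry <- (seq_len(d[2]) - voi$center["row"]) * s$volume$spacing[2] / voi$semi_short
    rx <- (seq_len(d[3]) - voi$center["col"]) * s$volume$spacing[3] / voi$semi_long
    inplane <- which(outer(ry^2, rx^2, `+`) <= 1)
    vox <- as.vector(outer(voi$slice_range, (inplane - 1L) * d[1], `+`))
    core <- s$instance_truth[[which(s$spec$names == tg)]]$core_voxels
    expect_true(all(vox %in% core))
  }
})

test_that("mean CT is exact on constant and noise-free phantom volumes", {
  v <- ct_volume(array(100, c(30, 40, 40)), c(1, 1, 1))
  voi <- fit_ellipse_voi(disk_region(15, 40, 40), c(1, 1))
  voi$slice_range <- 11:19
  m <- mean_ct(v, voi)
  expect_identical(m$mean_hu, 100)
  expect_gt(m$n_voxels, 0)

  s <- generate_phantom(phantom_spec(n_thoracic = 0, n_lumbar = 2,
                                     trabecular_hu = c(95, 95), noise_sd = 0,
                                     volume_shape = c(70, 48, 48)))
  lab <- label_vertebrae(s$class_mask)
  voi2 <- instance_voi(lab$instances[[1]], dim(s$volume$voxels), s$volume$spacing)
  expect_equal(mean_ct(s$volume, voi2)$mean_hu, 95)
})

test_that("mean CT over a z-ramp equals the ramp at the VOI z-centroid", {
  arr <- array(0, c(30, 40, 40))
  for (z in 1:30) arr[z, , ] <- 10 * z
  v <- ct_volume(arr, c(1, 1, 1))
  voi <- fit_ellipse_voi(disk_region(15, 40, 40), c(1, 1))
  voi$slice_range <- 11:19                 # symmetric about slice 15
  expect_equal(mean_ct(v, voi)$mean_hu, 150)
  voi$slice_range <- 28:36                 # out of bounds
  expect_error(mean_ct(v, voi), "bounds")
})
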