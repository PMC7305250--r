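test_that("axial rescale halves a 1-mm grid to 2 mm and preserves constants", {
  v <- ct_volume(array(37, c(4, 32, 32)), c(1, 1, 1))
  r <- rescale_axial(v, 2)
  expect_equal(dim(r$voxels), c(4, 16, 16))
  expect_equal(r$spacing, c(1, 2, 2))
  expect_true(all(abs(r$voxels - 37) < 1e-12))   # bilinear preserves constants
})

test_that("bilinear rescale reproduces affine ramps away from the border", {
  arr <- array(0, c(2, 40, 40))
  for (z in 1:2) arr[z, , ] <- matrix(seq_len(40), 40, 40)  # ramp along rows
  v <- ct_volume(arr, c(1, 1, 1))
  r <- rescale_axial(v, 2)
  sl <- r$voxels[1, , ]
  # interior rows of the output must remain an affine function of position
  interior <- 3:(nrow(sl) - 2)
  expect_lt(max(abs(diff(sl[interior, 10], differences = 2))), 1e-10)
})

test_that("rescale is idempotent at the target spacing and keeps masks integral", {
  v <- ct_volume(array(rnorm(4 * 30 * 30), c(4, 30, 30)), c(1, 1.5, 1.5))
  r1 <- rescale_axial(v, 2)
  r2 <- rescale_axial(r1, 2)
  expect_identical(r1$voxels, r2$voxels)
  m <- class_mask(array(sample(0:3, 4 * 30 * 30, TRUE), c(4, 30, 30)),
                  c(1, 1.5, 1.5))
  rm_ <- rescale_axial(m, 2)
  expect_type(rm_$labels, "integer")
  expect_true(all(rm_$labels %in% 0:3))
  expect_error(rescale_axial(m, 2, method = "bilinear"), "nearest")
})

test_that("body center is the centroid of the largest bright component", {
  sl <- matrix(-1000, 120, 100)
  sl[disk_region(20, 120, 100, center = c(60, 40))] <- 50
  fb <- find_body_center(sl, -200)
  expect_false(fb$degenerate)
  expect_lt(max(abs(fb$center - c(60, 40))), 0.5)

  # two components: centroid of the larger one wins
  sl[disk_region(8, 120, 100, center = c(30, 80))] <- 50
  big <- which(disk_region(20, 120, 100, center = c(60, 40)), arr.ind = TRUE)
  fb2 <- find_body_center(sl, -200)
  expect_lt(max(abs(fb2$center - colMeans(big))), 1e-9)

  # all air: geometric center, flagged
  fb3 <- find_body_center(matrix(-1000, 50, 60), -200)
  expect_true(fb3$degenerate)
  expect_equal(unname(fb3$center), c(25.5, 30.5))
})

test_that("centered crop selects the right window and pads with air", {
  arr <- array(seq_len(2 * 200 * 200), c(2, 200, 200))
  v <- ct_volume(arr, c(1, 1, 1))
  cr <- crop_centered(v, c(101, 101), 160)
  expect_equal(dim(cr$voxels), c(2, 160, 160))
  expect_equal(attr(cr, "crop_offset"), c(row = 21, col = 21))
  expect_equal(cr$voxels[, 1, 1], as.numeric(arr[, 21, 21]))
  expect_equal(cr$voxels[, 160, 160], as.numeric(arr[, 180, 180]))

  corner <- crop_centered(v, c(1, 1), 160)
  expect_equal(corner$voxels[1, 1, 1], -1000)  # padded region
  expect_equal(corner$voxels[, 81, 81], as.numeric(arr[, 1, 1]))
})

test_that("masks crop and back-project to their original coordinates", {
  s <- small_phantom()
  cr <- crop_centered(s$class_mask, c(24, 24), 32)
  back <- backproject_mask(cr, attr(cr, "crop_offset"), dim(s$class_mask$labels))
  inside <- array(FALSE, dim(s$class_mask$labels))
  inside[, 8:39, 8:39] <- TRUE
  expect_identical(back$labels[inside], s$class_mask$labels[inside])
  expect_true(all(back$labels[!inside] == 0L))
})

test_that("patch sampling covers every slice with clamped final offset", {
  v <- ct_volume(array(0, c(64, 8, 8)), c(1, 1, 1))
  p <- sample_patches(v, depth = 64, stride_z = 32)
  expect_length(p, 1)
  expect_equal(p[[1]]$z_offset, 0L)

  v100 <- ct_volume(array(0, c(100, 8, 8)), c(1, 1, 1))
  expect_equal(attr(sample_patches(v100, 64, 32), "offsets"), c(0L, 32L, 36L))

  # randomized coverage sweep
  set.seed(4)
  for (k in 1:25) {
    nz <- sample(5:120, 1); depth <- sample(4:70, 1); stride <- sample(seq_len(depth), 1)
    vk <- ct_volume(array(0, c(nz, 4, 4)), c(1, 1, 1))
    pk <- sample_patches(vk, depth, stride)
    covered <- sort(unique(unlist(lapply(pk, function(q)
      q$z_offset + seq_len(dim(q$data)[1])))))
    expect_true(all(seq_len(nz) %in% covered))
  }

  short <- sample_patches(ct_volume(array(7, c(10, 8, 8)), c(1, 1, 1)), 16, 8)
  expect_length(short, 1)
  expect_true(short[[1]]$padded)
  expect_equal(dim(short[[1]]$data), c(16, 8, 8))
  expect_equal(short[[1]]$data[11, 1, 1], -1000)
})

test_that("augmentation is identity at zero magnitude and seed-deterministic", {
  img <- array(rnorm(8 * 40 * 40), c(8, 40, 40))
  msk <- array(sample(0:3, 8 * 40 * 40, TRUE), c(8, 40, 40))
  a0 <- augment_patch(img, msk, translate_vox = 0, rotate_deg = 0, seed = 1)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)

  a1 <- augment_patch(img, msk, seed = 42)
  a2 <- augment_patch(img, msk, seed = 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_false(identical(a1$image, augment_patch(img, msk, seed = 43)$image))
})

test_that("rotating a disk mask by R then -R keeps Dice >= 0.95", {
  msk <- array(0L, c(2, 60, 60))
  msk[1, , ] <- msk[2, , ] <- disk_region(18, 60, 60) * 1L
  img <- msk * 100
  fwd <- augment_patch(img, msk, params = list(dy = 0, dx = 0, theta_deg = 10))
  bwd <- augment_patch(fwd$image, fwd$mask,
                       params = list(dy = 0, dx = 0, theta_deg = -10))
  d <- dice_coefficient(which(bwd$mask == 1L), which(msk == 1L))
  expect_gte(d, 0.95)
})
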