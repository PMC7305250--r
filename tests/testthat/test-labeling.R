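mask_of <- function(arr) class_mask(arr, c(1, 1, 1))

test_that("disjoint bodies become separate instances sorted superior-first", {
  arr <- array(0L, c(40, 20, 20))
  arr <- add_box(arr, 25:32, 5:12, 5:12, 3L)
  arr <- add_box(arr, 5:12, 5:12, 5:12, 3L)
  inst <- extract_components(mask_of(arr), min_voxels = 10)
  expect_length(inst, 2)
  expect_true(all(vapply(inst, `[[`, 0L, "class_id") == 3L))
  expect_lt(inst[[1]]$centroid[1], inst[[2]]$centroid[1])
  expect_equal(inst[[1]]$z_extent, c(5, 12))
})

test_that("majority vote sets the class of mixed components", {
  arr <- array(0L, c(20, 20, 20))
  arr <- add_box(arr, 5:10, 5:10, 5:10, 2L)
  arr[11, 5, 5:7] <- 1L                      # 3 stray voxels, attached
  inst <- extract_components(mask_of(arr), min_voxels = 10)
  expect_length(inst, 1)
  expect_equal(inst[[1]]$class_id, 2L)
})

test_that("speckle below min_voxels is discarded", {
  s <- small_phantom()
  arr <- s$class_mask$labels
  set.seed(9)
  stray <- sample(which(arr == 0L), 30)      # isolated single-voxel noise
  arr[stray] <- 1L
  inst <- extract_components(class_mask(arr, s$class_mask$spacing),
                             min_voxels = 100)
  expect_length(inst, length(s$instance_truth))
})

test_that("naming follows L1-top-down and T12-bottom-up rules", {
  mk <- function(classes) {
    # synthetic sorted instances with the given class ids
    lapply(seq_along(classes), function(i)
      list(name = NA_character_, class_id = classes[i], voxels = i,
           centroid = c(i * 10, 0, 0), z_extent = c(i * 10 - 2, i * 10 + 2),
           flags = character()))
  }
  full <- assign_names(mk(c(rep(1L, 6), rep(2L, 6), 3L, 3L)))
  expect_equal(vapply(full, `[[`, "", "name"), vertebra_levels())

  truncated <- assign_names(mk(c(rep(2L, 6), 3L, 3L)))
  expect_equal(vapply(truncated, `[[`, "", "name"),
               c(paste0("T", 7:12), "L1", "L2"))

  # 13 thoracic instances: bottom-up stops at T1, most superior flagged
  thirteen <- assign_names(mk(c(rep(1L, 7), rep(2L, 6), 3L)))
  expect_true(is.na(thirteen[[1]]$name))
  expect_true("extra_thoracic" %in% thirteen[[1]]$flags)
  expect_equal(vapply(thirteen[-1], `[[`, "", "name"),
               c(paste0("T", 1:12), "L1"))

  # a third lumbar instance is flagged, not named
  three_l <- assign_names(mk(c(2L, 3L, 3L, 3L)))
  expect_true(is.na(three_l[[4]]$name))
  expect_true("extra_lumbar" %in% three_l[[4]]$flags)

  # no lumbar anchor: most inferior thoracic becomes T12, low confidence
  no_l <- assign_names(mk(c(2L, 2L)))
  expect_equal(vapply(no_l, `[[`, "", "name"), c("T11", "T12"))
  expect_true("no_lumbar_anchor" %in% no_l[[2]]$flags)
})

test_that("phantom ground-truth masks are named correctly under FOV truncation", {
  set.seed(11)
  full <- generate_phantom(phantom_spec(noise_sd = 0))
  d <- dim(full$class_mask$labels)
  truth_names <- vapply(full$instance_truth, `[[`, "", "name")
  for (k in 1:8) {
    # random superior truncation that always keeps L1 and L2 intact
    l1_top <- min(arrayInd(full$instance_truth[[13]]$voxels, d)[, 1])
    z0 <- sample(1:(l1_top - 60), 1)
    arr <- full$class_mask$labels[z0:d[1], , , drop = FALSE]
    inst <- assign_names(extract_components(class_mask(arr, full$class_mask$spacing)))
    got <- vapply(inst, `[[`, "", "name")
    kept <- vapply(full$instance_truth, function(t)
      min(arrayInd(t$voxels, d)[, 1]) >= z0, TRUE)
    # every fully retained vertebra must get its true name back
    expect_true(all(truth_names[kept] %in% got))
    # and name order must be monotone in centroid z
    expect_true(all(diff(vertebra_order(got[!is.na(got)])) > 0))
  }
})

test_that("instance masks render and round trip; overlaps are rejected", {
  s <- small_phantom()
  lab <- label_vertebrae(s$class_mask)
  im <- lab$instance_mask
  expect_setequal(names(im$mapping), s$spec$names)
  for (i in seq_along(s$instance_truth)) {
    tr <- s$instance_truth[[i]]
    id <- im$mapping[[tr$name]]
    expect_setequal(which(im$labels == id), tr$voxels)
  }
  empty <- to_instance_mask(list(), c(4, 4, 4))
  expect_true(all(empty$labels == 0L))
  a <- list(name = "L1", voxels = 1:10)
  b <- list(name = "L2", voxels = 5:15)
  expect_error(to_instance_mask(list(a, b), c(4, 4, 4)), "overlap")
})
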