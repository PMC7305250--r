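tiny_net <- function(seed = 5, growth = 4, base = 6)
  build_dense_unet(unet_config(n_levels = 2, layers_per_dense_block = c(2, 2, 2),
                               growth_rate = growth, base_channels = base),
                   seed = seed)

test_that("forward pass yields same-sized 4-class probabilities summing to 1", {
  net <- tiny_net()
  patch <- array(rnorm(8 * 16 * 16, 0, 300), c(8, 16, 16))
  fw <- unet_forward(net, patch)
  expect_equal(dim(fw$prob), c(4, 8 * 16 * 16))
  expect_lt(max(abs(colSums(fw$prob) - 1)), 1e-5)
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  # test-scale input shape from the constructor contract
  fw2 <- unet_forward(tiny_net(), array(0, c(16, 32, 32)))
  expect_equal(dim(fw2$prob), c(4, 16 * 32 * 32))
})

test_that("dense blocks grow the concatenated features by the growth rate", {
  g <- 8
  net <- build_dense_unet(unet_config(n_levels = 2,
                                      layers_per_dense_block = c(3, 2, 2),
                                      growth_rate = g, base_channels = 6))
  # layer j of a dense block consumes c0 + (j-1)*g channels and emits g
  expect_equal(dim(net$params$enc1_conv1_W), c(g, 1, 27))
  expect_equal(dim(net$params$enc1_conv2_W), c(g, 1 + g, 27))
  expect_equal(dim(net$params$enc1_conv3_W), c(g, 1 + 2 * g, 27))
  # block output passes a 1x1x1 reduction fed with all concatenated channels
  expect_equal(dim(net$params$enc1_bott_W), c(6, 1 + 3 * g))
})

test_that("construction-time divisibility check rejects odd input dims", {
  net <- tiny_net()
  expect_error(unet_forward(net, array(0, c(7, 16, 16))), "divisible")
})

test_that("Dice loss matches its closed form", {
  # perfect one-hot prediction
  truth <- c(0L, 1L, 2L, 3L, 1L)
  P <- matrix(0, 4, 5); P[cbind(truth + 1L, 1:5)] <- 1
  expect_lt(dice_loss(P, truth), 1e-4)
  # total miss: one-hot of a wrong class everywhere
  Pm <- matrix(0, 4, 5); Pm[cbind((truth + 1L) %% 4 + 1L, 1:5)] <- 1
  expect_gt(dice_loss(Pm, truth), 0.99)
  # uniform prediction on a 2-voxel toy, hand-evaluated soft Dice
  Pu <- matrix(0.25, 4, 2)
  tu <- c(1L, 0L)
  eps <- 1e-5
  d1 <- (2 * 0.25 + eps) / (0.5 + 1 + eps)      # class 1: one true voxel
  d23 <- (0 + eps) / (0.5 + 0 + eps)            # classes 2,3: absent
  expect_equal(dice_loss(Pu, tu), 1 - mean(c(d1, d23, d23)), tolerance = 1e-12)
})

test_that("analytic gradients point downhill", {
  net <- tiny_net(seed = 9)
  patch <- array(rnorm(4 * 8 * 8, 0, 300), c(4, 8, 8))
  truth <- array(sample(0:3, 4 * 8 * 8, TRUE), c(4, 8, 8))
  fw <- unet_forward(net, patch, keep_cache = TRUE)
  l0 <- dice_loss(fw$prob, truth)
  g <- unet_backward(net, fw, truth)
  expect_setequal(names(g), names(net$params))
  stepped <- net
  for (k in names(g)) stepped$params[[k]] <- stepped$params[[k]] - 0.05 * g[[k]]
  l1 <- dice_loss(unet_forward(stepped, patch)$prob, truth)
  expect_lt(l1, l0)
})

test_that("learning rate halves after three non-improving epochs", {
  expect_equal(lr_schedule(c(.5, .5, .5, .5)), c(1e-4, 1e-4, 1e-4, 5e-5))
  expect_equal(lr_schedule(c(.5, .6, .7, .8, .9)), rep(1e-4, 5))
  # two consecutive plateaus halve twice; improvement resets the counter
  expect_equal(lr_schedule(c(.5, .5, .5, .5, .5, .5, .5)),
               c(1e-4, 1e-4, 1e-4, 5e-5, 5e-5, 5e-5, 2.5e-5))
  expect_equal(lr_schedule(c(.5, .5, .5, .6, .6, .6, .6)),
               c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 5e-5))
})

test_that("training runs, records history, and is seed-reproducible", {
  expect_error(train_dense_unet(tiny_net(), list(), list()), "empty")
  patch <- lapply(1:3, function(i) array(rnorm(4 * 8 * 8, 0, 200), c(4, 8, 8)))
  truth <- lapply(1:3, function(i) {
    a <- array(0L, c(4, 8, 8)); a[, 3:6, 3:6] <- 1L; a
  })
  n1 <- train_dense_unet(tiny_net(), patch, truth, max_epochs = 2,
                         lr0 = 1e-3, seed = 3)
  expect_equal(n1$history$epoch, 1:2)
  expect_true(all(is.finite(n1$history$loss)))
  expect_equal(n1$history$lr, c(1e-3, 1e-3))
  n2 <- train_dense_unet(tiny_net(), patch, truth, max_epochs = 2,
                         lr0 = 1e-3, seed = 3)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("volume prediction equals the argmax of a single forward pass", {
  net <- tiny_net()
  v <- ct_volume(array(rnorm(8 * 16 * 16, 0, 300), c(8, 16, 16)), c(1, 2, 2))
  pred <- predict_volume(net, v, depth = 8, stride_z = 8)
  fw <- unet_forward(net, v$voxels)
  manual <- array(apply(fw$prob, 2, which.max) - 1L, dim(v$voxels))
  expect_identical(as.vector(pred$labels), as.vector(manual))
})

test_that("oracle-stub inference reproduces the ground truth exactly", {
  s <- small_phantom()
  net <- oracle_net(s$class_mask)
  # overlapping patches all agree, so argmax-of-average == the truth
  pred <- predict_volume(net, s$volume, depth = 16, stride_z = 7)
  expect_identical(pred$labels, s$class_mask$labels)
})
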