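test_that("local variance matches the brute-force window oracle", {
  set.seed(42)
  for (rep in 1:3) {
    band <- matrix(rnorm(400), 20, 20)
    for (w in c(3L, 7L)) {
      expect_equal(localVariance(band, w), bruteLocalVariance(band, w),
                   tolerance = 1e-10)
    }
  }
})

test_that("local variance handles constants, impulses and known windows", {
  expect_true(all(localVariance(matrix(3.7, 12, 12), 7L) == 0))
  ## 7x7 window of 25 ones and 24 zeros: population variance (25/49)(24/49)
  band <- matrix(0, 13, 13)
  band[4:10, 4:10][1:25] <- 1
  lv <- localVariance(band, 7L)
  expect_equal(lv[7, 7], (25 / 49) * (24 / 49), tolerance = 1e-12)
  ## single impulse of height h: centre variance h^2 * 48 / 49^2
  h <- 2.5
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- h
  lvImp <- localVariance(imp, 7L)
  expect_equal(lvImp[8, 8], h^2 * 48 / 49^2, tolerance = 1e-12)
  expect_equal(lvImp, bruteLocalVariance(imp, 7L), tolerance = 1e-12)
})

test_that("local variance rejects even windows and excludes nodata", {
  band <- matrix(rnorm(100), 10, 10)
  expect_error(localVariance(band, 4L), "odd")
  band[3, 3] <- NA
  lv <- localVariance(band, 3L)
  expect_equal(lv, bruteLocalVariance(band, 3L), tolerance = 1e-12)
  allNa <- matrix(NA_real_, 8, 8)
  expect_true(all(is.na(localVariance(allNa, 3L))))
})

test_that("feature assembly follows raster order, drops nodata, attaches labels", {
  sim <- simulateScene(smallSceneConfig(seed = 5L, width = 12L, height = 9L))
  ft <- assembleFeatures(sim$scene, sim$labels)
  expect_identical(dim(ft), c(9L * 12L, 4L))
  expect_identical(ft@labels, sim$labels@labels[ft@pixelIndex])
  ## raster scan order: rows sorted by (row, col)
  expect_true(!is.unsorted(order(ft@pixelIndex[, 1], ft@pixelIndex[, 2])))
  expect_identical(ft@pixelIndex[1:3, 2], 1:3)
  ## texture column equals the window oracle at the same pixels
  lv <- bruteLocalVariance(sim$scene@nir, 7L)
  expect_equal(ft@values[, "texture"], lv[ft@pixelIndex], tolerance = 1e-10)
  ## nodata pixels drop out
  scene <- sim$scene
  scene@green[1, 1:5] <- NA
  scene@nodataMask[1, 1:5] <- TRUE
  expect_identical(nrow(assembleFeatures(scene)@values), 9L * 12L - 5L)
  ## shape mismatch is an input error
  badLabels <- generatePatchMask(smallSceneConfig(width = 5L, height = 5L))
  expect_error(assembleFeatures(sim$scene, badLabels), "match")
})

test_that("balanced sampling is exact, deterministic and guarded", {
  sim <- simulateScene(smallSceneConfig(seed = 1L, width = 128L, height = 128L))
  ft <- assembleFeatures(sim$scene, sim$labels)
  s1 <- balancedSample(ft, perClass = 1434L, seed = 10L)
  expect_identical(nrow(s1@values), 2868L)
  expect_identical(sum(s1@labels == 1L), 1434L)
  s2 <- balancedSample(ft, perClass = 1434L, seed = 10L)
  expect_identical(s1@pixelIndex, s2@pixelIndex)
  expect_identical(nrow(balancedSample(ft, perClass = 0L)@values), 0L)
  expect_error(balancedSample(ft, perClass = nrow(ft@values)), "only")
})

test_that("stratified 70/30 split reproduces the calibration arithmetic", {
  sim <- simulateScene(smallSceneConfig(seed = 1L, width = 128L, height = 128L))
  ft <- assembleFeatures(sim$scene, sim$labels)
  sample <- balancedSample(ft, perClass = 1434L, seed = 1L)
  parts <- splitFeatures(sample, trainFraction = 0.70, seed = 2L)
  expect_identical(nrow(parts$train@values), 2008L)
  expect_identical(nrow(parts$test@values), 860L)
  expect_identical(sum(parts$train@labels == 1L), 1004L)
  expect_identical(sum(parts$train@labels == 2L), 1004L)
  ## partition: train and test together recover the sample exactly
  expect_identical(nrow(parts$train@values) + nrow(parts$test@values),
                   nrow(sample@values))
  both <- rbind(parts$train@pixelIndex, parts$test@pixelIndex)
  expect_identical(nrow(unique(both)), nrow(sample@values))
  ## per-class proportions within 1 pixel of the global fraction
  for (cls in 1:2) {
    expect_lte(abs(sum(parts$train@labels == cls) -
                   0.7 * sum(sample@labels == cls)), 1)
  }
  ## extreme fraction still leaves a non-empty test set
  tiny <- subsetFeatureTable(sample, 1:8)
  p <- splitFeatures(tiny, trainFraction = 0.999, seed = 1L)
  expect_gt(nrow(p$test@values), 0L)
  expect_error(splitFeatures(assembleFeatures(sim$scene), 0.7), "labelled")
})

test_that("standardization centres the training targets and inverts cleanly", {
  sim <- simulateScene(smallSceneConfig(seed = 2L, width = 64L, height = 64L))
  ft <- assembleFeatures(sim$scene, sim$labels)
  targets <- subsetFeatureTable(ft, which(ft@labels == 1L))
  std <- standardizeFeatures(targets)
  z <- applyStandardization(targets, std)
  expect_true(all(abs(colMeans(z@values)) < 1e-10))
  expect_equal(unname(apply(z@values, 2, sd)), rep(1, 4), tolerance = 1e-10)
  ## invert: z * scale + center reproduces the original values
  back <- sweep(sweep(z@values, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, targets@values, tolerance = 1e-12)
  ## constant feature column is a data error
  flat <- targets
  flat@values[, "texture"] <- 1
  expect_error(standardizeFeatures(flat), "zero spread")
})
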