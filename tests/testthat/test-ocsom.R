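test_that("fraction threshold reproduces the sorted-midpoint rule", {
  expect_identical(fractionThreshold(1:10, 0.8), 8.5)
  ## the 99% fraction of 100 distinct values: midpoint of the top two
  set.seed(2)
  v <- sample(seq(1, 300, by = 3))
  s <- sort(v)
  expect_identical(fractionThreshold(v, 0.99), (s[99] + s[100]) / 2)
  ## independent order-statistic re-implementation on random multisets
  for (rep in 1:10) {
    d <- sample(round(rexp(50), 2), 50, replace = TRUE)
    f <- runif(1, 0.1, 0.9)
    k <- floor(f * 50 + 0.5)
    expect_identical(fractionThreshold(d, f),
                     (sort(d)[k] + sort(d)[k + 1]) / 2)
  }
  expect_error(fractionThreshold(1:10, 0.01), "degenerate")
  expect_error(fractionThreshold(1:10, 0.999), "degenerate")
  expect_error(fractionThreshold(3, 0.5), "at least 2")
})

test_that("BMU search matches an exhaustive scan with index tie-break", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4)
  m <- fitOcSom(x, rows = 3L, cols = 3L, epochs = 3L, seed = 1L)
  ## identity: a codebook is its own BMU with distance 0
  b <- bmuDistance(m, m@codebooks[5L, ])
  expect_identical(b$unit, 5L)
  expect_equal(b$distanceSq, 0, tolerance = 1e-20)
  ## random inputs: exhaustive scan oracle
  for (rep in 1:10) {
    v <- rnorm(4)
    d2 <- apply(m@codebooks, 1, function(cb) sum((cb - v)^2))
    got <- bmuDistance(m, v)
    expect_identical(got$unit, which.min(d2))
    expect_equal(got$distanceSq, min(d2), tolerance = 1e-12)
  }
  ## midway between two identical-distance units: lowest index wins
  tie <- m
  tie@codebooks <- rbind(rep(0, 4), rep(1, 4))
  tie@gridRows <- 2L; tie@gridCols <- 1L
  tie@gridCoords <- cbind(1:2, c(1L, 1L))
  expect_identical(bmuDistance(tie, rep(0.5, 4))$unit, 1L)
  expect_error(bmuDistance(m, 1:3), "dimension")
})

test_that("SOM training is deterministic and shrinks quantization error", {
  set.seed(6)
  x <- matrix(rnorm(400), 100, 4)
  m1 <- fitOcSom(x, rows = 4L, cols = 4L, epochs = 10L, seed = 3L)
  m2 <- fitOcSom(x, rows = 4L, cols = 4L, epochs = 10L, seed = 3L)
  expect_identical(m1@codebooks, m2@codebooks)
  ## longer training does not degrade the fit (tolerance for online noise)
  short <- fitOcSom(x, rows = 4L, cols = 4L, epochs = 5L, seed = 3L)
  long <- fitOcSom(x, rows = 4L, cols = 4L, epochs = 40L, seed = 3L)
  mq <- function(m) mean(somQuantizationError(m, x))
  expect_lt(mq(long), mq(short) * 1.05)
  expect_error(fitOcSom(x, epochs = 0L), "epoch")
})

test_that("a 1x1 SOM converges to the data mean", {
  set.seed(8)
  x <- matrix(rnorm(300 * 4, mean = 2, sd = 0.3), 300, 4)
  m <- fitOcSom(x, rows = 1L, cols = 1L, epochs = 40L, seed = 2L,
                finalRate = 0.005)
  expect_lt(max(abs(m@codebooks[1, ] - colMeans(x)) / abs(colMeans(x))),
            0.01)
})

test_that("a 2x1 SOM with shrinking neighbourhood finds both cluster means", {
  x <- twoClusters(n = 80L, sep = 6, seed = 4L, sd = 0.15)
  m <- fitOcSom(x, rows = 2L, cols = 1L, epochs = 40L, seed = 5L,
                finalRadius = 0.05, finalRate = 0.005)
  km <- kmeans(x, centers = rbind(rep(0, 4), rep(6, 4)))
  ## match codebooks to k-means centres by proximity
  for (u in 1:2) {
    nearest <- which.min(rowSums((km$centers - matrix(m@codebooks[u, ], 2, 4,
                                                      byrow = TRUE))^2))
    relErr <- sqrt(sum((m@codebooks[u, ] - km$centers[nearest, ])^2)) /
      sqrt(sum(km$centers[nearest, ]^2) + 1)
    expect_lt(relErr, 0.05)
  }
})

test_that("calibration realizes the configured acceptance fraction", {
  set.seed(9)
  x <- matrix(rnorm(400 * 4), 400, 4)
  m <- calibrateSom(fitOcSom(x, seed = 1L), x, fractionTargets = 0.95)
  codes <- classifyFeatures(m, x)
  expect_lte(abs(mean(codes == 2L) - 0.05), 1 / nrow(x) + 1e-12)
  ## exactly round(fraction * N) training points fall at or below d
  d <- somQuantizationError(m, x)
  expect_identical(sum(d <= m@threshold), as.integer(round(0.95 * 400)))
  ## a point exactly at the threshold is a target (novelty needs > d)
  expect_identical(ifelse(d <= m@threshold, 1L, 2L), classifyFeatures(m, x))
  ## a distant cluster is entirely novel
  far <- matrix(rnorm(40 * 4, mean = 20), 40, 4)
  expect_true(all(classifyFeatures(m, far) == 2L))
  ## classifying with an uncalibrated model is a state error
  expect_error(classifyFeatures(fitOcSom(x, seed = 1L), x), "threshold")
})

test_that("the calibration-scale grid sweep stays well-behaved", {
  set.seed(10)
  x <- matrix(rnorm(2008 * 4), 2008, 4)
  elapsed <- system.time({
    for (g in c(3L, 8L, 20L)) {
      m <- fitOcSom(x, rows = g, cols = g, epochs = 2L, seed = 1L)
      expect_identical(nrow(m@codebooks), g * g)
    }
  })["elapsed"]
  expect_lt(elapsed, 60)
})
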