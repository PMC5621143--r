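## Minimal hand-built model for forward-pass checks.
handAeModel <- function(W1, b1, W2, b2) {
  new("AeModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      lossTrace = numeric(0), threshold = NA_real_,
      fractionTargets = NA_real_, standardization = list())
}

test_that("forward pass matches hand arithmetic", {
  ## all-zero weights: output is the decoder bias for every input
  m0 <- handAeModel(matrix(0, 4, 2), c(0, 0), matrix(0, 2, 4),
                    c(0.3, -0.1, 0.2, 0.5))
  for (rep in 1:3) {
    expect_equal(aeForward(m0, rnorm(4)), c(0.3, -0.1, 0.2, 0.5),
                 tolerance = 1e-15)
  }
  ## 1-hidden-unit network with hand-set weights, pencil-and-paper forward
  w1 <- matrix(c(0.2, -0.1, 0.4, 0.3), 4, 1)
  w2 <- matrix(c(1.5, -0.5, 0.25, 2), 1, 4)
  m1 <- handAeModel(w1, 0.1, w2, rep(0.05, 4))
  x <- c(1, 2, -1, 0.5)
  hval <- 1 / (1 + exp(-(sum(w1 * x) + 0.1)))
  expect_equal(aeForward(m1, x), as.numeric(w2) * hval + 0.05,
               tolerance = 1e-12)
  expect_error(aeForward(m1, 1:3), "dimension")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(31)
  for (rep in 1:3) {
    d <- 4L; hidden <- sample(2:4, 1)
    x <- matrix(rnorm(12 * d), 12, d)
    W1 <- matrix(rnorm(d * hidden, sd = 0.5), d, hidden)
    b1 <- rnorm(hidden, sd = 0.2)
    W2 <- matrix(rnorm(hidden * d, sd = 0.5), hidden, d)
    b2 <- rnorm(d, sd = 0.2)
    gr <- aeGradients(W1, b1, W2, b2, x)
    eps <- 1e-6
    lossAt <- function(W1, b1, W2, b2) aeGradients(W1, b1, W2, b2, x)$loss
    numCheck <- function(analytic, perturb) {
      for (k in seq_len(min(6, length(analytic)))) {
        num <- (do.call(lossAt, perturb(k, eps)) -
                  do.call(lossAt, perturb(k, -eps))) / (2 * eps)
        denom <- max(abs(analytic[k]), 1e-4)
        expect_lt(abs(num - analytic[k]) / denom, 1e-5)
      }
    }
    numCheck(gr$dW1, function(k, e) {
      W <- W1; W[k] <- W[k] + e; list(W, b1, W2, b2) })
    numCheck(gr$db1, function(k, e) {
      b <- b1; b[k] <- b[k] + e; list(W1, b, W2, b2) })
    numCheck(gr$dW2, function(k, e) {
      W <- W2; W[k] <- W[k] + e; list(W1, b1, W, b2) })
    numCheck(gr$db2, function(k, e) {
      b <- b2; b[k] <- b[k] + e; list(W1, b1, W2, b) })
  }
})

test_that("training reduces loss monotonically at small learning rate", {
  set.seed(37)
  x <- matrix(rnorm(50 * 4), 50, 4)
  m <- fitAutoencoder(x, hidden = 4L, epochs = 300L, learningRate = 1e-3,
                      seed = 1L)
  expect_true(all(diff(m@lossTrace) <= 1e-12))
  expect_lt(m@lossTrace[300], m@lossTrace[1])
})

test_that("a 1-unit autoencoder approaches the 1-component PCA residual", {
  set.seed(41)
  t <- rnorm(200, sd = 1)
  dir <- c(1, 1, 1, 1) / 2
  x <- outer(t, dir) + matrix(rnorm(800, sd = 0.05), 200, 4)
  m <- fitAutoencoder(x, hidden = 1L, epochs = 8000L, learningRate = 0.05,
                      seed = 2L)
  aeErr <- mean(noveltyScores(m, x))
  p <- fitOcPca(x, nComponents = 1L, outlierFraction = 0.1)
  pcaErr <- mean(pcaReconstructionError(p, x))
  expect_lt(aeErr, 2 * pcaErr)
})

test_that("a full-width autoencoder beats the best constant predictor", {
  set.seed(43)
  x <- matrix(rnorm(50 * 4), 50, 4)
  m <- fitAutoencoder(x, hidden = 4L, epochs = 3000L, seed = 3L)
  constLoss <- sum(apply(x, 2, function(col) mean((col - mean(col))^2)))
  expect_lt(m@lossTrace[length(m@lossTrace)], constLoss)
})

test_that("fits are deterministic and thresholds behave by construction", {
  set.seed(47)
  x <- matrix(rnorm(200 * 4), 200, 4)
  m1 <- fitAutoencoder(x, epochs = 200L, seed = 5L)
  m2 <- fitAutoencoder(x, epochs = 200L, seed = 5L)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@threshold, m2@threshold)
  codes <- classifyFeatures(m1, x)
  expect_lte(abs(mean(codes == 2L) - 0.05), 1 / nrow(x) + 1e-12)
  expect_true(all(noveltyScores(m1, x) >= 0))
  ## constant network: any input reconstructing to itself scores zero
  mc <- handAeModel(matrix(0, 4, 2), c(0, 0), matrix(0, 2, 4), rep(0.2, 4))
  mc@threshold <- 0.1
  expect_equal(aeScore(mc, rep(0.2, 4)), 0, tolerance = 1e-20)
  expect_identical(classifyFeatures(mc, matrix(0.2, 1, 4)), 1L)
})

test_that("off-manifold outliers are rejected", {
  set.seed(53)
  t <- rnorm(300, sd = 2)
  basis <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  x <- outer(t, basis[, 1]) + matrix(rnorm(1200, sd = 0.1), 300, 4)
  m <- fitAutoencoder(x, hidden = 2L, epochs = 4000L, seed = 7L)
  ## shift 10 sd along a direction the code cannot represent
  outliers <- x[1:30, ] + matrix(10 * 0.1 * basis[, 4], 30, 4, byrow = TRUE) * 10
  expect_true(all(classifyFeatures(m, outliers) == 2L))
})

test_that("training guards its preconditions", {
  x <- matrix(rnorm(80), 20, 4)
  expect_error(fitAutoencoder(x[1:5, ]), "at least 10")
  expect_error(fitAutoencoder(x, hidden = 0L), "hidden")
  expect_error(fitAutoencoder(x, learningRate = -1), "positive")
  expect_error(fitAutoencoder(x, learningRate = 50), "diverged")
})
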