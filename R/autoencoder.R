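#' Autoencoder forward pass
#'
#' `decoder(sigmoid(encoder(x)))`: sigmoid hidden layer, linear output.
#' The linear read-out is deliberate on standardized features — a sigmoid
#' output could never reproduce values outside (0, 1) — and with one hidden
#' layer the network converges toward a principal-component-like subspace
#' description of the target class.
#'
#' @param model an [AeModel-class] (fitted or freshly initialized).
#' @param x a feature vector or matrix of rows in the model's coordinates.
#' @return reconstruction with the same shape as `x`.
#' @export
aeForward <- function(model, x) {
  stopifnot(is(model, "AeModel"))
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(m) != nrow(model@W1)) {
    stop("input dimension ", ncol(m), " does not match encoder (",
         nrow(model@W1), ")")
  }
  h <- plogis(sweep(m %*% model@W1, 2L, model@b1, "+"))
  out <- sweep(h %*% model@W2, 2L, model@b2, "+")
  if (is.matrix(x)) out else as.numeric(out)
}

## Loss and analytic gradients of the mean-per-sample squared
## reconstruction error; shared by training and the finite-difference
## tests.
aeGradients <- function(W1, b1, W2, b2, x) {
  n <- nrow(x)
  h <- plogis(sweep(x %*% W1, 2L, b1, "+"))
  xhat <- sweep(h %*% W2, 2L, b2, "+")
  e <- xhat - x
  loss <- sum(e^2) / n
  dOut <- 2 * e / n
  dW2 <- crossprod(h, dOut)
  db2 <- colSums(dOut)
  dH <- dOut %*% t(W2) * h * (1 - h)
  dW1 <- crossprod(x, dH)
  db1 <- colSums(dH)
  list(loss = loss, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Fit a one-class autoencoder
#'
#' Trains a single-hidden-layer autoencoder (default 8 sigmoid hidden
#' units, linear output) to reproduce target-class feature vectors by
#' full-batch gradient descent on the mean squared reconstruction error,
#' then calibrates the novelty threshold at the [fractionThreshold()] of
#' the training reconstruction errors. Weights are initialized from a
#' seeded uniform distribution on `[-0.5, 0.5] / sqrt(fan_in)`, so the fit
#' is deterministic given the seed.
#'
#' @param trainTargets a [FeatureTable-class] (standardized upstream) or
#'   numeric matrix of target-class rows.
#' @param hidden hidden-unit count, default 8.
#' @param epochs gradient steps, default 3000.
#' @param learningRate step size, default 0.05.
#' @param fractionTargets accepted training fraction, default 0.95.
#' @param seed integer seed for weight initialization.
#' @return a fitted, thresholded [AeModel-class].
#' @export
fitAutoencoder <- function(trainTargets, hidden = 8L, epochs = 3000L,
                           learningRate = 0.05, fractionTargets = 0.95,
                           seed = 1L) {
  x <- featureValues(trainTargets)
  if (hidden < 1L) stop("need at least one hidden unit")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (nrow(x) < 10L) stop("autoencoder training needs at least 10 rows")
  d <- ncol(x)
  init <- withSeed(deriveSeed(seed, 5L), {
    list(W1 = matrix(runif(d * hidden, -0.5, 0.5) / sqrt(d), d, hidden),
         b1 = runif(hidden, -0.5, 0.5) / sqrt(d),
         W2 = matrix(runif(hidden * d, -0.5, 0.5) / sqrt(hidden), hidden, d),
         b2 = runif(d, -0.5, 0.5) / sqrt(hidden))
  })
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    gr <- aeGradients(W1, b1, W2, b2, x)
    if (!is.finite(gr$loss)) {
      stop("autoencoder training diverged (loss became non-finite); ",
           "try a smaller learningRate")
    }
    trace[e] <- gr$loss
    W1 <- W1 - learningRate * gr$dW1
    b1 <- b1 - learningRate * gr$db1
    W2 <- W2 - learningRate * gr$dW2
    b2 <- b2 - learningRate * gr$db2
  }
  model <- new("AeModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
               lossTrace = trace, threshold = NA_real_,
               fractionTargets = fractionTargets,
               standardization = featureStandardization(trainTargets))
  err <- aeErrors(model, x)
  model@threshold <- fractionThreshold(err, fractionTargets)
  model
}

#' Autoencoder novelty score
#'
#' Squared reconstruction error `||x - aeForward(x)||^2`; target objects
#' reconstruct with small error, off-manifold outliers with large error.
#'
#' @param model a fitted [AeModel-class].
#' @param x a feature vector in the model's coordinates.
#' @return non-negative score.
#' @export
aeScore <- function(model, x) {
  aeErrors(model, if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L))
}

aeErrors <- function(model, m) {
  rowSums((m - aeForward(model, m))^2)
}

#' @describeIn noveltyScores squared autoencoder reconstruction error.
#' @export
setMethod("noveltyScores", "AeModel", function(model, features) {
  aeErrors(model, modelMatrix(model, features))
})

setMethod("show", "AeModel", function(object) {
  cat("AeModel (one-class autoencoder)\n",
      " architecture:", nrow(object@W1), "->", ncol(object@W1),
      "(sigmoid) ->", ncol(object@W2), "(linear)\n",
      " final training loss:",
      signif(object@lossTrace[length(object@lossTrace)], 6), "\n",
      " threshold:", if (is.na(object@threshold)) "unset" else
        signif(object@threshold, 6), "\n")
})
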