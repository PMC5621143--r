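#' Gaussian radial basis kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / sigma^2)`. Note the spread enters as
#' `sigma^2` in the denominator (no factor 2), so `K = exp(-1)` exactly when
#' the squared distance equals `sigma^2`.
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma positive spread parameter.
#' @return similarity in (0, 1\]; `K(x, x) = 1`.
#' @export
rbfKernel <- function(x, z, sigma) {
  if (length(x) != length(z)) {
    stop("kernel arguments have lengths ", length(x), " and ", length(z))
  }
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((x - z)^2) / sigma^2)
}

## Full RBF Gram matrix between row sets.
rbfCross <- function(a, b, sigma) exp(-crossDistSq(a, b) / sigma^2)

#' Fit a Support Vector Data Description (one-class SVM)
#'
#' Finds the minimal enclosing hypersphere of the target-class training data
#' in RBF feature space by solving the SVDD dual
#' \deqn{\max_\alpha \sum_i \alpha_i K(x_i, x_i)
#'       - \sum_{ij} \alpha_i \alpha_j K(x_i, x_j)
#'   \quad \mathrm{s.t.}\ \sum_i \alpha_i = 1,\ 0 \le \alpha_i \le C,}
#' with box constraint `C = 1 / (N * nu)` tying the penalty to the expected
#' outlier-fraction bound `nu`. The solver is SMO-style pairwise coordinate
#' ascent on the simplex-with-box feasible set: at each step, mass moves
#' from the maximal-gradient coefficient that can decrease to the
#' minimal-gradient coefficient that can grow, with the exact 1-D optimum
#' clipped to the box.
#'
#' Two radii are produced. The decision threshold (`threshold` slot) is
#' calibrated as the order-statistic midpoint of the training distances at
#' fraction `1 - nu` (see [fractionThreshold()]), making the training
#' rejection rate equal `nu` to within `1/N` and unifying thresholding with
#' the other detectors. The classical boundary-support-vector radius is also
#' computed and stored in `boundaryRadiusSq` for comparison.
#'
#' @param trainTargets a [FeatureTable-class] of target-class training rows
#'   (standardized upstream), or a plain numeric matrix.
#' @param sigma RBF spread, default 2.5 (on standardized features).
#' @param nu expected outlier-fraction bound in (0, 1), default 0.05.
#' @param tol convergence tolerance on the KKT gradient gap.
#' @param maxIter maximum SMO iterations.
#' @return a fitted [SvddModel-class].
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' colnames(x) <- c("a", "b")
#' m <- fitSvdd(cbind(x, x), nu = 0.2)
#' @export
fitSvdd <- function(trainTargets, sigma = 2.5, nu = 0.05,
                    tol = 1e-8, maxIter = 200000L) {
  x <- featureValues(trainTargets)
  n <- nrow(x)
  if (n < 2L) stop("SVDD needs at least 2 training points")
  if (sigma <= 0) stop("sigma must be positive")
  if (nu <= 0 || nu >= 1) stop("nu must lie strictly in (0, 1)")
  C <- 1 / (n * nu)
  if (C * n < 1) {
    stop("infeasible configuration: C * N = ", C * n,
         " < 1 leaves the simplex constraint unsatisfiable")
  }
  K <- rbfCross(x, x, sigma)
  alpha <- rep(1 / n, n)          # feasible start (1/n <= C since nu < 1)
  g <- 2 * as.vector(K %*% alpha) # gradient of alpha' K alpha
  eps <- 1e-12
  iter <- 0L
  repeat {
    iter <- iter + 1L
    down <- alpha > eps            # can give mass away
    up <- alpha < C - eps          # can receive mass
    i <- which(down)[which.max(g[down])]
    j <- which(up)[which.min(g[up])]
    gap <- g[i] - g[j]
    if (gap < tol) break
    if (iter > maxIter) {
      stop("SVDD solver failed to converge within ", maxIter,
           " iterations (KKT gap ", signif(gap, 4), ")")
    }
    denom <- 2 * (K[i, i] + K[j, j] - 2 * K[i, j])
    tmax <- min(alpha[i], C - alpha[j])
    t <- if (denom > eps) min(gap / denom, tmax) else tmax
    alpha[i] <- alpha[i] - t
    alpha[j] <- alpha[j] + t
    g <- g + 2 * t * (K[, j] - K[, i])
  }
  offset <- as.numeric(alpha %*% K %*% alpha)
  supportTol <- 1e-9
  sv <- alpha > supportTol
  model <- new("SvddModel",
               supportPoints = x[sv, , drop = FALSE],
               alphas = alpha[sv], sigma = sigma, offset = offset,
               boundaryRadiusSq = NA_real_, nTrain = n, nu = nu,
               threshold = NA_real_, fractionTargets = 1 - nu,
               standardization = featureStandardization(trainTargets))
  model@C <- C   # set via slot: `C =` would partially match new()'s Class arg
  trainDist <- svddDistanceSq(model, x)  # x already in model coordinates
  model@threshold <- fractionThreshold(trainDist, 1 - nu)
  boundary <- sv & alpha > supportTol & alpha < C - 1e-6
  model@boundaryRadiusSq <- if (any(boundary)) {
    stats::median(trainDist[boundary])
  } else {
    model@threshold
  }
  model
}

#' Squared kernel distance to the SVDD sphere centre
#'
#' `||v - a||^2 = K(v, v) - 2 sum_i alpha_i K(x_i, v) + offset` where the
#' centre `a = sum_i alpha_i x_i` lives in feature space and
#' `offset = sum_ij alpha_i alpha_j K(x_i, x_j)` is cached at fit time.
#'
#' @param model a fitted [SvddModel-class].
#' @param v a feature vector (length 4 in pipeline use) or matrix of rows,
#'   already in the model's standardized coordinates.
#' @return non-negative squared distances.
#' @export
svddDistanceSq <- function(model, v) {
  stopifnot(is(model, "SvddModel"))
  if (!nrow(model@supportPoints)) stop("model has no support points; fit it first")
  m <- if (is.matrix(v)) v else matrix(as.numeric(v), nrow = 1L)
  if (ncol(m) != ncol(model@supportPoints)) {
    stop("feature dimension ", ncol(m), " does not match the model's ",
         ncol(model@supportPoints))
  }
  scoreBlocked(m, 50000L, function(block) {
    kv <- rbfCross(block, model@supportPoints, model@sigma)
    d2 <- 1 - 2 * as.vector(kv %*% model@alphas) + model@offset
    pmax(d2, 0)
  })
}

#' @describeIn noveltyScores squared kernel distance to the SVDD centre.
#' @export
setMethod("noveltyScores", "SvddModel", function(model, features) {
  svddDistanceSq(model, modelMatrix(model, features))
})

setMethod("show", "SvddModel", function(object) {
  cat("SvddModel (one-class SVM / SVDD)\n",
      " sigma", object@sigma, "| nu", object@nu,
      "| C", signif(object@C, 4), "\n",
      " support vectors:", length(object@alphas), "of", object@nTrain, "\n",
      " calibrated R^2:", signif(object@threshold, 6),
      "| boundary-SV R^2:", signif(object@boundaryRadiusSq, 6), "\n")
})

## Apply `f` to row blocks of m, concatenating results; bounds the memory
## of kernel cross matrices on whole-mosaic inputs.
scoreBlocked <- function(m, blockRows, f) {
  n <- nrow(m)
  if (n <= blockRows) return(f(m))
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + blockRows - 1L, n)
    out[start:end] <- f(m[start:end, , drop = FALSE])
    start <- end + 1L
  }
  out
}

## Accept either a FeatureTable or a bare matrix as training input.
featureValues <- function(x) {
  if (is(x, "FeatureTable")) x@values else as.matrix(x)
}

featureStandardization <- function(x) {
  if (is(x, "FeatureTable")) x@standardization else list()
}
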