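# Shared fixtures and independent oracles, built in code at test time.

smallSceneConfig <- function(seed = 1L, width = 96L, height = 96L, ...) {
  sceneConfig(width = width, height = height, seed = seed, ...)
}

## Brute-force local variance with reflect padding: per-pixel window
## enumeration, independent of the boxSum implementation.
bruteLocalVariance <- function(band, window) {
  r <- (window - 1L) %/% 2L
  n <- nrow(band); p <- ncol(band)
  reflect <- function(i, len) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > len, 2L * len + 1L - i, i)
  }
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      ri <- reflect(i + (-r):r, n)
      ci <- reflect(j + (-r):r, p)
      vals <- as.vector(band[ri, ci])
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        out[i, j] <- mean(vals^2) - mean(vals)^2
      }
    }
  }
  out
}

## Reference SVDD dual via kernlab's interior-point QP solver:
## min alpha' K alpha - diag(K)' alpha s.t. sum(alpha) = 1, 0 <= alpha <= C.
ipopSvddObjective <- function(x, sigma, C) {
  skip_if_not_installed("kernlab")
  K <- exp(-as.matrix(dist(x))^2 / sigma^2)
  n <- nrow(K)
  sol <- kernlab::ipop(c = -diag(K), H = 2 * K,
                       A = matrix(1, 1, n), b = 1, r = 0,
                       l = rep(0, n), u = rep(C, n),
                       sigf = 9, maxiter = 200)
  a <- kernlab::primal(sol)
  sum(diag(K) * a) - as.numeric(a %*% K %*% a)
}

svddDualObjective <- function(model, x, sigma) {
  ## recompute the dual objective from a fitted model's full alpha vector
  ## support points only (non-supports contribute ~0)
  a <- model@alphas
  xs <- model@supportPoints
  K <- exp(-as.matrix(dist(xs))^2 / sigma^2)
  sum(a) * 1 - as.numeric(a %*% K %*% a)  # K(x,x) = 1 under RBF
}

## Tight two-cluster data for SOM / outlier tests.
twoClusters <- function(n = 60L, d = 4L, sep = 6, seed = 1L, sd = 0.1) {
  set.seed(seed)
  rbind(matrix(rnorm(n * d, 0, sd), ncol = d),
        matrix(rnorm(n * d, sep, sd), ncol = d))
}

## Histogram overlap coefficient of two samples on common breaks.
overlapCoefficient <- function(a, b, bins = 60L) {
  breaks <- seq(min(a, b), max(a, b), length.out = bins + 1L)
  pa <- hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  pb <- hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}

## Mean connected-component size of a logical mask (4-connectivity),
## independent flood-fill oracle (EBImage::bwlabel cross-checks it where
## available).
meanComponentSize <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    n <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% n + 1L
      j <- (cur - 1L) %/% n + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1L] >= 1L && nb[1L] <= n && nb[2L] >= 1L &&
            nb[2L] <= ncol(mask)) {
          pos <- (nb[2L] - 1L) * n + nb[1L]
          if (mask[pos] && lab[pos] == 0L) {
            lab[pos] <- comp
            queue <- c(queue, pos)
          }
        }
      }
    }
  }
  sum(mask) / comp
}
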