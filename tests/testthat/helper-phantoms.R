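# Shared small fixtures, built in code.

# Desk-scale phantom: 96x96 frames at 0.15 mm, 60 slices over 35 mm.
smallPhantomSpec <- function(strictureLengthMm = 14, strictureDepth = 0.8,
                             speckleSigma = 0, psfSigmaPx = 0,
                             fibrosisPattern = "dotted", seed = 1L,
                             frames = 60L, frameShape = c(96L, 96L)) {
  PhantomSpec(
    geometry = AcquisitionGeometry(35, frames / 10, 10, c(0.15, 0.15)),
    frameShape = frameShape,
    lumenRadiusMm = 1.8, spongiosumRadiusMm = 4.2,
    strictureLengthMm = strictureLengthMm, strictureDepth = strictureDepth,
    fibrosisPattern = fibrosisPattern,
    speckleSigma = speckleSigma, psfSigmaPx = psfSigmaPx, seed = seed)
}

# Tiny isotropic phantom for rendering tests (0.2 mm cubic voxels).
renderPhantomSpec <- function(fibrosisPattern = "dotted", seed = 2L) {
  PhantomSpec(
    geometry = AcquisitionGeometry(8, 4, 10, c(0.2, 0.2)),
    frameShape = c(40L, 40L),
    lumenRadiusMm = 1.2, spongiosumRadiusMm = 3,
    strictureCenterMm = 4, strictureLengthMm = 4, strictureDepth = 0.8,
    fibrosisPattern = fibrosisPattern,
    speckleSigma = 0, psfSigmaPx = 0, seed = seed)
}

# Brute-force nearest-neighbour HD95 oracle: all pairwise distances,
# percentile by the linear-interpolation formula, written independently
# of the package internals.
oracleHd95 <- function(a, b, spacing = NULL, percentile = 0.95) {
  boundary <- function(m) {
    d <- dim(m)
    keep <- matrix(FALSE, 0, length(d))
    idx <- which(m, arr.ind = TRUE)
    onBoundary <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      nb <- TRUE
      for (ax in seq_along(d)) {
        for (s in c(-1L, 1L)) {
          q <- p; q[ax] <- q[ax] + s
          if (any(q < 1L) || any(q > d)) { onBoundary[r] <- TRUE; next }
          if (!m[matrix(q, 1)]) onBoundary[r] <- TRUE
        }
      }
    }
    idx[onBoundary, , drop = FALSE]
  }
  nd <- length(dim(a))
  if (is.null(spacing)) spacing <- rep(1, nd)
  ba <- boundary(a) %*% diag(spacing, nd)
  bb <- boundary(b) %*% diag(spacing, nd)
  dmat <- matrix(0, nrow(ba), nrow(bb))
  for (i in seq_len(nrow(ba)))
    for (j in seq_len(nrow(bb)))
      dmat[i, j] <- sqrt(sum((ba[i, ] - bb[j, ])^2))
  pooled <- sort(c(apply(dmat, 1, min), apply(dmat, 2, min)))
  # percentile with linear interpolation between order statistics
  h <- (length(pooled) - 1) * percentile + 1
  lo <- floor(h)
  hi <- min(lo + 1, length(pooled))
  pooled[lo] + (h - lo) * (pooled[hi] - pooled[lo])
}

randomMask <- function(n = 12L, p = 0.3) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  if (!any(m)) m[sample(n * n, 1)] <- TRUE
  m
}
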