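#' @include AllClasses.R
NULL

.asMask <- function(x) {
  if (is.null(dim(x))) stop("mask must be an array")
  x != 0
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for two same-shaped binary masks. Two empty
#' masks agree perfectly and score 1.
#'
#' @param pred,truth binary (logical or 0/1) arrays of identical shape.
#' @return coefficient in \[0, 1\].
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' diceCoefficient(a, a)  # 1
#' @export
diceCoefficient <- function(pred, truth) {
  pred <- .asMask(pred); truth <- .asMask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between masks")
  sa <- sum(pred); sb <- sum(truth)
  if (sa + sb == 0) return(1)
  2 * sum(pred & truth) / (sa + sb)
}

# Boundary pixels: mask pixels with a 4-adjacent (2D) / 6-adjacent (3D)
# non-mask neighbour; pixels on the array border count as boundary.
.boundaryMask <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  interiorAll <- array(TRUE, dim = d)
  for (ax in seq_len(nd)) {
    idxLo <- lapply(d, seq_len); idxLo[[ax]] <- c(1L, seq_len(d[ax] - 1L))
    idxHi <- lapply(d, seq_len); idxHi[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    lo <- do.call(`[`, c(list(mask), idxLo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(mask), idxHi, list(drop = FALSE)))
    interiorAll <- interiorAll & array(lo, d) & array(hi, d)
    # array edges: out-of-bounds counts as non-mask
    edge <- lapply(d, seq_len)
    edgeMask <- array(FALSE, dim = d)
    idx1 <- edge; idx1[[ax]] <- 1L
    idxN <- edge; idxN[[ax]] <- d[ax]
    eval1 <- do.call(`[<-`, c(list(edgeMask), idx1, list(TRUE)))
    edgeMask <- do.call(`[<-`, c(list(eval1), idxN, list(TRUE)))
    interiorAll <- interiorAll & !edgeMask
  }
  mask & !interiorAll
}

.boundaryCoords <- function(mask) which(.boundaryMask(mask), arr.ind = TRUE)

# Nearest-neighbour Euclidean distances from each row of `a` to the point
# set `b` (both n x d coordinate matrices, already spacing-scaled).
# Chunked so the pairwise block never exceeds ~8e6 doubles.
.nnDistances <- function(a, b) {
  nb <- nrow(b)
  bb <- rowSums(b^2)
  chunk <- max(1L, floor(8e6 / nb))
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    ablock <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ablock^2), bb, "+") - 2 * ablock %*% t(b)
    d2min <- apply(d2, 1, min)
    d2min[d2min < 1e-9] <- 0  # cancellation residue on coincident points
    out[i:j] <- sqrt(d2min)
    i <- j + 1L
  }
  out
}

# Integer voxel offsets within physical radius (rLo, rHi], sorted by
# their spacing-scaled Euclidean length.
.offsetShell <- function(rLo, rHi, spacing) {
  rng <- lapply(spacing, function(s) {
    m <- ceiling(rHi / s)
    (-m):m
  })
  grid <- as.matrix(do.call(expand.grid, rng))
  d <- sqrt(colSums((t(grid) * spacing)^2))
  keep <- d > rLo & d <= rHi
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d)
  list(off = grid[o, , drop = FALSE], dist = d[o])
}

# Exact nearest-boundary distances from voxel coordinates `aCoords` to
# the point set marked TRUE in `bMask`, scanning integer offsets in
# nondecreasing physical distance (the first hit is the minimum). The
# search radius doubles until every point is resolved; far outliers fall
# back to pairwise distances.
.nnDistGrid <- function(aCoords, bMask, spacing) {
  d <- dim(bMask)
  nd <- length(d)
  n <- nrow(aCoords)
  out <- rep(NA_real_, n)
  remaining <- seq_len(n)
  rLo <- -1e-9
  rHi <- 2 * max(spacing)
  rMax <- sqrt(sum((d * spacing)^2))
  while (length(remaining) > 0L && rLo < rMax) {
    sh <- .offsetShell(rLo, rHi, spacing)
    if (nrow(sh$off) * length(remaining) > 4e7) break  # shell too costly
    for (oi in seq_len(nrow(sh$off))) {
      if (length(remaining) == 0L) break
      cand <- aCoords[remaining, , drop = FALSE] +
        matrix(sh$off[oi, ], length(remaining), nd, byrow = TRUE)
      ok <- rep(TRUE, length(remaining))
      for (ax in seq_len(nd))
        ok <- ok & cand[, ax] >= 1L & cand[, ax] <= d[ax]
      hit <- ok
      if (any(ok))
        hit[ok] <- bMask[cand[ok, , drop = FALSE]]
      if (any(hit)) {
        out[remaining[hit]] <- sh$dist[oi]
        remaining <- remaining[!hit]
      }
    }
    rLo <- rHi
    rHi <- rHi * 2
  }
  if (length(remaining) > 0L) {
    bc <- which(bMask, arr.ind = TRUE)
    out[remaining] <- .nnDistances(
      aCoords[remaining, , drop = FALSE] %*% diag(spacing, nd),
      bc %*% diag(spacing, nd))
  }
  out
}

# Pooled directed nearest-neighbour boundary distances between two masks;
# brute force for small problems, grid search for volume-scale ones.
.pooledBoundaryDistances <- function(bndA, bndB, spacing) {
  ca <- which(bndA, arr.ind = TRUE)
  cb <- which(bndB, arr.ind = TRUE)
  nd <- length(dim(bndA))
  if (as.double(nrow(ca)) * nrow(cb) <= 4e6) {
    sa <- ca %*% diag(spacing, nd)
    sb <- cb %*% diag(spacing, nd)
    c(.nnDistances(sa, sb), .nnDistances(sb, sa))
  } else {
    c(.nnDistGrid(ca, bndB, spacing), .nnDistGrid(cb, bndA, spacing))
  }
}

# Percentile by linear interpolation between order statistics
# (conventions differ between toolkits, so the choice is pinned here).
.percentileLinear <- function(x, p) {
  unname(stats::quantile(x, p, type = 7))
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Boundary pixels of each mask (pixels 4/6-adjacent to a non-mask pixel,
#' array borders included) are extracted, the two directed
#' nearest-neighbour distance sets (A to B and B to A, Euclidean,
#' spacing-scaled) are pooled, and the 95th percentile of the pooled
#' distances is returned using linear interpolation between order
#' statistics. The pooled-percentile convention (rather than the max of
#' two directed percentiles) is the common medical-imaging choice and is
#' pinned by oracle tests. An empty mask leaves the metric undefined and
#' raises an error; it is never reported as 0.
#'
#' @param pred,truth binary arrays of identical shape, both non-empty.
#' @param spacing physical size per pixel along each axis (defaults to 1).
#' @param percentile percentile of the pooled distances (default 0.95;
#'   1 gives the exact Hausdorff distance).
#' @return distance >= 0 (same units as `spacing`).
#' @export
hd95 <- function(pred, truth, spacing = NULL, percentile = 0.95) {
  pred <- .asMask(pred); truth <- .asMask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between masks")
  if (sum(pred) == 0 || sum(truth) == 0)
    stop("undefined metric: HD95 requires both masks to be non-empty")
  nd <- length(dim(pred))
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd) stop("'spacing' must match mask dimensionality")
  pooled <- .pooledBoundaryDistances(.boundaryMask(pred), .boundaryMask(truth),
                                     spacing)
  .percentileLinear(pooled, percentile)
}

#' Evaluate a predicted label volume against ground truth
#'
#' Binarizes each requested class against the rest and computes DICE and
#' HD95 per class, plus the mean over the evaluated (foreground) classes.
#' A class absent from truth or prediction gets a flagged row with
#' undefined (NA) metrics and is excluded from the mean.
#'
#' @param pred,truth [LabelVolume-class] objects on the same grid.
#' @param classes integer class codes to evaluate (default 1:3, the
#'   foreground tissues).
#' @return data.frame with columns `class`, `className`, `dice`,
#'   `hd95_px`, `hd95_mm`, `defined`; the last row is the mean over
#'   defined classes (`class = NA`, `className = "mean"`).
#' @export
evaluateSegmentation <- function(pred, truth, classes = 1:3) {
  stopifnot(is(pred, "LabelVolume"), is(truth, "LabelVolume"))
  if (!identical(dim(pred@labels), dim(truth@labels)))
    stop("shape mismatch between predicted and truth volumes")
  if (!isTRUE(all.equal(pred@voxelMm, truth@voxelMm)))
    stop("voxel size mismatch between predicted and truth volumes")
  nm <- names(.CLS)[match(classes, .CLS)]
  rows <- lapply(seq_along(classes), function(ii) {
    cls <- classes[ii]
    p <- pred@labels == cls
    t <- truth@labels == cls
    if (sum(t) == 0 || sum(p) == 0) {
      return(data.frame(class = cls, className = nm[ii], dice = NA_real_,
                        hd95_px = NA_real_, hd95_mm = NA_real_,
                        defined = FALSE))
    }
    data.frame(class = cls, className = nm[ii],
               dice = diceCoefficient(p, t),
               hd95_px = hd95(p, t),
               hd95_mm = hd95(p, t, spacing = truth@voxelMm),
               defined = TRUE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$defined
  mean_row <- data.frame(class = NA_integer_, className = "mean",
                         dice = if (any(ok)) mean(tab$dice[ok]) else NA_real_,
                         hd95_px = if (any(ok)) mean(tab$hd95_px[ok]) else NA_real_,
                         hd95_mm = if (any(ok)) mean(tab$hd95_mm[ok]) else NA_real_,
                         defined = any(ok))
  rbind(tab, mean_row)
}
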