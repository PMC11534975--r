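#' @include AllClasses.R resize.R phantom.R
NULL

#' Split a dataset into training, validation and test sets
#'
#' Sizes follow the round-val/test, remainder-train convention: every
#' ratio after the first gets `round(ratio * n)` items and the first
#' (training) set takes the remainder. At the default 6:2:2 this is the
#' only rounding rule consistent with sizes 442/148/148 for n = 738.
#' Assignment is a uniform random permutation, reproducible under a
#' fixed seed. When `groups` is given, whole groups are kept inside a
#' single split (frames from one subject never straddle splits) and the
#' target sizes are met approximately.
#'
#' @param n number of items.
#' @param ratios positive proportions summing to 1 (default
#'   `c(0.6, 0.2, 0.2)` for train/val/test).
#' @param seed RNG seed for the assignment.
#' @param groups optional length-`n` group ids (e.g. subject ids).
#' @return named list of index vectors (`train`, `val`, `test` for three
#'   ratios), disjoint and jointly exhaustive.
#' @examples
#' lengths(splitDataset(738))  # 442, 148, 148
#' @export
splitDataset <- function(n, ratios = c(0.6, 0.2, 0.2), seed = 0L,
                         groups = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < length(ratios))
    stop("'n' must be at least the number of splits")
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("'ratios' must be positive and sum to 1")
  k <- length(ratios)
  nm <- if (k == 3L) c("train", "val", "test") else paste0("split", seq_len(k))
  sizes <- integer(k)
  if (k > 1L) sizes[-1L] <- round(ratios[-1L] * n)
  sizes[1L] <- n - sum(sizes[-1L])
  if (any(sizes < 0)) stop("ratios produce a negative split size")
  if (is.null(groups)) {
    perm <- .withSeed(seed, sample.int(n))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    out <- lapply(seq_len(k), function(i)
      if (sizes[i] == 0L) integer(0) else sort(perm[starts[i]:ends[i]]))
  } else {
    if (length(groups) != n) stop("'groups' must have length n")
    gs <- split(seq_len(n), groups)
    ord <- .withSeed(seed, sample.int(length(gs)))
    assigned <- rep(1L, length(gs))
    filled <- integer(k)
    for (gi in ord) {
      # place each group where the deficit against its target is largest
      deficit <- (sizes - filled) / pmax(sizes, 1L)
      s <- which.max(deficit)
      assigned[gi] <- s
      filled[s] <- filled[s] + length(gs[[gi]])
    }
    out <- lapply(seq_len(k), function(s)
      sort(unlist(gs[assigned == s], use.names = FALSE)))
  }
  names(out) <- nm
  out
}

#' Preprocess a frame for segmentation
#'
#' Bilinear resize to the network input size (256 x 256 by default) and
#' min-max normalization to \[0, 1\]; a constant frame maps to all-zero.
#'
#' @param frame 2D numeric matrix.
#' @param size target `c(rows, cols)`.
#' @return matrix of dimension `size` with values in \[0, 1\].
#' @export
preprocessFrame <- function(frame, size = c(256L, 256L)) {
  if (is.null(dim(frame)) || length(dim(frame)) != 2L)
    stop("'frame' must be a 2D array")
  out <- bilinearResize(frame, size)
  rng <- range(out)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(out)))
  (out - rng[1]) / (rng[2] - rng[1])
}

# Two-threshold Otsu on a 256-bin histogram: exhaustive search over
# threshold pairs maximizing the between-class variance, vectorized over
# the second threshold.
.otsuMulti <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(c(rng[1], rng[1]))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(nbins, findInterval(x, br, rightmost.closed = TRUE)),
                nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  W <- cumsum(p)
  M <- cumsum(p * mids)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(nbins - 2L)) {
    j <- (i + 1L):(nbins - 1L)
    w0 <- W[i]; m0 <- M[i]
    w1 <- W[j] - w0; m1 <- M[j] - m0
    w2 <- 1 - W[j]; m2 <- M[nbins] - M[j]
    v <- ifelse(w0 > 0, m0^2 / w0, 0) +
      ifelse(w1 > 0, m1^2 / pmax(w1, 1e-300), 0) +
      ifelse(w2 > 0, m2^2 / pmax(w2, 1e-300), 0)
    vmax <- max(v)
    if (vmax > best) {
      best <- vmax
      bi <- i
      bj <- j[which.max(v)]
    }
  }
  c(br[bi + 1L], br[bj + 1L])
}

# Keep the connected components of `mask` that touch `marker`: the fixed
# point of geodesic dilation of marker within mask, in one labelling pass.
.geodesicReconstruct <- function(marker, mask) {
  if (!any(mask) || !any(marker)) return(array(FALSE, dim = dim(mask)))
  lbl <- EBImage::bwlabel(mask)
  keep <- setdiff(unique(lbl[marker & mask]), 0)
  array(lbl %in% keep, dim = dim(mask))
}

#' Deterministic classical 4-class segmentation of one frame
#'
#' A fully deterministic baseline standing in the place a trained network
#' occupies in the clinical pipeline. The frame is banded into
#' dark/mid/bright by two-threshold Otsu; the most central dark connected
#' component (subject to plausibility guards on size) is the fluid-filled
#' lumen; the band of the tissue ring immediately surrounding the lumen
#' defines the corpus spongiosum, recovered by geodesic reconstruction
#' within that band; any strictly brighter pixels inside the filled
#' lumen+spongiosum region are periurethral fibrosis; everything else is
#' background. Frames without a plausible dark component yield no lumen
#' pixels, which is a valid output.
#'
#' @param frame preprocessed 2D frame in \[0, 1\] (see
#'   [preprocessFrame()]).
#' @param minLumenPx minimum plausible lumen component size (pixels).
#' @param maxLumenFrac maximum plausible lumen area as a fraction of the
#'   frame.
#' @return integer matrix of class codes (see [tissueClasses()]).
#' @export
segmentClassical <- function(frame, minLumenPx = 9L, maxLumenFrac = 0.25) {
  d <- dim(frame)
  out <- array(0L, dim = d)
  rng <- range(frame)
  if (rng[2] - rng[1] <= 1e-12) return(out)  # no structure
  th <- .otsuMulti(frame)
  dark <- frame <= th[1]
  mid <- frame > th[1] & frame <= th[2]
  bright <- frame > th[2]
  if (!any(dark)) return(out)
  lbl <- EBImage::bwlabel(dark)
  nComp <- max(lbl)
  if (nComp == 0) return(out)
  sizes <- tabulate(lbl[lbl > 0], nComp)
  ctr <- (d + 1) / 2
  rows <- row(lbl); cols <- col(lbl)
  # centroid distance to frame centre per component
  cr <- vapply(seq_len(nComp), function(i) mean(rows[lbl == i]), numeric(1))
  cc <- vapply(seq_len(nComp), function(i) mean(cols[lbl == i]), numeric(1))
  distc <- sqrt((cr - ctr[1])^2 + (cc - ctr[2])^2)
  ok <- sizes >= minLumenPx & sizes <= maxLumenFrac * prod(d)
  if (!any(ok)) return(out)
  lumenId <- which(ok)[which.min(distc[ok])]
  lumen <- lbl == lumenId
  ring <- EBImage::dilate(lumen, EBImage::makeBrush(9, "disc")) & !lumen
  if (!any(ring & (mid | bright))) {  # lumen floating in the dark band
    out[lumen] <- .CLS[["lumen"]]
    return(out)
  }
  # the sleeve around the lumen is whichever band reconstructs to the
  # larger region from the ring (edge-transition pixels can put a thin
  # sliver of the other band between lumen and sleeve)
  fromMid <- .geodesicReconstruct(ring & mid, mid)
  fromBright <- .geodesicReconstruct(ring & bright, bright)
  if (sum(fromMid) >= sum(fromBright)) {
    spong <- fromMid
    fibCand <- bright
  } else {
    spong <- fromBright
    fibCand <- array(FALSE, dim = d)  # nothing brighter than the sleeve
  }
  region <- EBImage::fillHull(lumen | spong) > 0
  fib <- fibCand & region
  out[spong] <- .CLS[["spongiosum"]]
  out[fib] <- .CLS[["fibrosis"]]
  out[lumen] <- .CLS[["lumen"]]
  out
}

#' Segment a whole frame stack into a label volume
#'
#' Each frame is preprocessed to the model input size, segmented by the
#' requested backend, and the label map is resized back to the native
#' frame shape with nearest-neighbour interpolation (labels stay
#' integral). The result is assembled on the stack's geometry.
#'
#' @param stack a [FrameStack-class].
#' @param backend `"classical"` for [segmentClassical()], or a trained
#'   model from [trainUnet()].
#' @param inputSize segmentation working resolution (default 256 x 256;
#'   a model backend imposes its own training resolution).
#' @return a [LabelVolume-class] co-registered with
#'   `assembleVolume(stack)`.
#' @export
segmentStack <- function(stack, backend = "classical",
                         inputSize = c(256L, 256L)) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@frames)
  isModel <- inherits(backend, "unetModel")
  if (!isModel && !identical(backend, "classical"))
    stop("configuration error: backend must be \"classical\" or a trained unet model")
  if (isModel) inputSize <- backend$config$inputSize
  labels <- array(0L, dim = d)
  for (k in seq_len(d[3])) {
    fr <- preprocessFrame(stack@frames[, , k], inputSize)
    seg <- if (isModel) predictUnet(backend, fr) else segmentClassical(fr)
    labels[, , k] <- nearestResize(seg, d[1:2])
  }
  g <- stack@geometry
  LabelVolume(labels, c(g@pixelMm, sliceSpacing(g)))
}
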