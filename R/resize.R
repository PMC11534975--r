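#' @include AllClasses.R
NULL

# Center-aligned sample coordinates: output pixel i (1-based) samples the
# input at (i - 0.5) * in/out + 0.5 in 1-based pixel-centre coordinates.
# With this mapping a 2x downsample of a 1-px checkerboard averages each
# 2x2 block exactly.
.sampleCoords <- function(nOut, nIn) {
  (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
}

#' Bilinear image resize
#'
#' Separable bilinear interpolation with centre-aligned coordinate
#' mapping (output and input pixel grids share their physical extent).
#' Samples beyond the input grid are clamped to the edge pixels.
#'
#' @param image 2D numeric matrix.
#' @param size target `c(rows, cols)`.
#' @return resized matrix.
#' @export
bilinearResize <- function(image, size) {
  d <- dim(image)
  if (is.null(d) || length(d) != 2L) stop("'image' must be a 2D matrix")
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) stop("invalid target size")
  if (all(size == d)) return(image)
  interp1 <- function(n, nIn) {
    x <- pmin(pmax(.sampleCoords(n, nIn), 1), nIn)
    lo <- pmin(floor(x), nIn - 1L); lo[nIn == 1L] <- 1L
    w <- x - lo
    list(lo = as.integer(lo), hi = as.integer(pmin(lo + 1L, nIn)), w = w)
  }
  r <- interp1(size[1], d[1])
  cc <- interp1(size[2], d[2])
  # rows first
  m <- image[r$lo, , drop = FALSE] * (1 - r$w) + image[r$hi, , drop = FALSE] * r$w
  m[, cc$lo, drop = FALSE] * rep(1 - cc$w, each = size[1]) +
    m[, cc$hi, drop = FALSE] * rep(cc$w, each = size[1])
}

#' Nearest-neighbour label resize
#'
#' Resizes an integer label image without ever creating fractional
#' classes: each output pixel copies the nearest input pixel under the
#' same centre-aligned mapping as [bilinearResize()].
#'
#' @param labels 2D integer matrix.
#' @param size target `c(rows, cols)`.
#' @return resized integer matrix.
#' @export
nearestResize <- function(labels, size) {
  d <- dim(labels)
  if (is.null(d) || length(d) != 2L) stop("'labels' must be a 2D matrix")
  size <- as.integer(size)
  if (all(size == d)) return(labels)
  ri <- as.integer(pmin(pmax(round(.sampleCoords(size[1], d[1])), 1L), d[1]))
  ci <- as.integer(pmin(pmax(round(.sampleCoords(size[2], d[2])), 1L), d[2]))
  labels[ri, ci, drop = FALSE]
}
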