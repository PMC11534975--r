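#' @include AllClasses.R
NULL

#' Construct a TransferFunction
#'
#' Defaults follow the package's rendering convention: the urethral
#' lumen is fully transparent (opacity 0), so lumen voxels never
#' contribute colour and in-lumen reflection/reverberation artefacts
#' disappear from the rendering; the corpus spongiosum is a warm
#' semi-transparent gray; periurethral fibrosis gets a green colormap
#' with a markedly higher opacity than every other class; background is
#' transparent.
#'
#' @param colors 4 x 3 RGB matrix (rows: background, lumen, spongiosum,
#'   fibrosis).
#' @param opacity per-class opacity per unit voxel of ray travel.
#' @param intensityModulated scale sample colour by voxel intensity.
#' @param background RGB background colour.
#' @return a [TransferFunction-class].
#' @export
TransferFunction <- function(colors = rbind(background = c(0, 0, 0),
                                            lumen = c(0, 0, 0),
                                            spongiosum = c(0.85, 0.75, 0.65),
                                            fibrosis = c(0.1, 0.9, 0.2)),
                             opacity = c(background = 0, lumen = 0,
                                         spongiosum = 0.04, fibrosis = 0.45),
                             intensityModulated = TRUE,
                             background = c(0, 0, 0)) {
  new("TransferFunction", colors = unname(as.matrix(colors)),
      opacity = unname(opacity),
      intensityModulated = intensityModulated,
      background = background)
}

#' Construct an orthographic Camera
#'
#' @param azimuthDeg rotation of the view direction about the
#'   elevational (slice) axis, degrees.
#' @param elevationDeg tilt towards the elevational axis, degrees
#'   (90 looks straight down the urethra).
#' @param imageSize rendered image `c(height, width)` in pixels.
#' @param stepVoxels ray sampling step in units of the smallest voxel
#'   dimension, in (0, 1].
#' @return a [Camera-class].
#' @export
Camera <- function(azimuthDeg = 0, elevationDeg = 0,
                   imageSize = c(128L, 128L), stepVoxels = 0.5) {
  new("Camera", azimuthDeg = as.numeric(azimuthDeg),
      elevationDeg = as.numeric(elevationDeg),
      imageSize = as.integer(imageSize), stepVoxels = as.numeric(stepVoxels))
}

#' Zero out lumen voxel intensities
#'
#' Sets the intensity of every lumen-coded voxel to 0 (equivalently,
#' makes them fully transparent), removing reflection and reverberation
#' artefacts from inside the water-filled lumen; all other voxels are
#' unchanged.
#'
#' @param volume a [SonoVolume-class].
#' @param labels a co-registered [LabelVolume-class].
#' @return a new [SonoVolume-class].
#' @export
applyLumenTransparency <- function(volume, labels) {
  stopifnot(is(volume, "SonoVolume"), is(labels, "LabelVolume"))
  if (!identical(dim(volume@voxels), dim(labels@labels)))
    stop("shape mismatch between volume and labels")
  v <- volume@voxels
  v[labels@labels == .CLS[["lumen"]]] <- 0
  SonoVolume(v, volume@voxelMm)
}

# Orthonormal camera frame in physical (mm) coordinates
# axes: x = row axis, y = col axis, z = slice (elevational) axis.
.cameraBasis <- function(camera) {
  az <- camera@azimuthDeg * pi / 180
  el <- camera@elevationDeg * pi / 180
  d <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  right <- c(-sin(az), cos(az), 0)
  up <- c(d[2] * right[3] - d[3] * right[2],
          d[3] * right[1] - d[1] * right[3],
          d[1] * right[2] - d[2] * right[1])
  list(dir = d, right = right, up = up / sqrt(sum(up^2)))
}

# trilinear sample of a 3D array at fractional 1-based voxel-centre
# coordinates (n x 3); coordinates outside the grid return `fill`
.trilinear <- function(a, f, fill = 0) {
  d <- dim(a)
  inb <- f[, 1] >= 1 & f[, 1] <= d[1] &
    f[, 2] >= 1 & f[, 2] <= d[2] &
    f[, 3] >= 1 & f[, 3] <= d[3]
  out <- rep(fill, nrow(f))
  if (!any(inb)) return(out)
  g <- f[inb, , drop = FALSE]
  lo <- pmin(pmax(floor(g), 1), matrix(rep(d - 1L, each = nrow(g)), ncol = 3))
  lo[, d == 1] <- 1
  w <- g - lo
  hi <- pmin(lo + 1, matrix(rep(d, each = nrow(g)), ncol = 3))
  at <- function(i, j, k) a[cbind(i, j, k)]
  v <- at(lo[, 1], lo[, 2], lo[, 3]) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    at(hi[, 1], lo[, 2], lo[, 3]) * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    at(lo[, 1], hi[, 2], lo[, 3]) * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    at(hi[, 1], hi[, 2], lo[, 3]) * w[, 1] * w[, 2] * (1 - w[, 3]) +
    at(lo[, 1], lo[, 2], hi[, 3]) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    at(hi[, 1], lo[, 2], hi[, 3]) * w[, 1] * (1 - w[, 2]) * w[, 3] +
    at(lo[, 1], hi[, 2], hi[, 3]) * (1 - w[, 1]) * w[, 2] * w[, 3] +
    at(hi[, 1], hi[, 2], hi[, 3]) * w[, 1] * w[, 2] * w[, 3]
  out[inb] <- v
  out
}

.nearestLabel <- function(a, f, fill = 0L) {
  d <- dim(a)
  r <- floor(f + 0.5)  # round half up: voxel i owns faces [i-0.5, i+0.5)
  inb <- r[, 1] >= 1 & r[, 1] <= d[1] &
    r[, 2] >= 1 & r[, 2] <= d[2] &
    r[, 3] >= 1 & r[, 3] <= d[3]
  out <- rep(fill, nrow(f))
  if (any(inb)) out[inb] <- a[r[inb, , drop = FALSE]]
  out
}

#' Emission-absorption raycasting of a labelled volume
#'
#' Parallel (orthographic) rays are cast through the volume with
#' front-to-back alpha compositing: intensity is sampled trilinearly,
#' class labels with nearest-neighbour, per-sample colour is the class
#' colour (optionally scaled by the interpolated intensity) and
#' per-sample opacity is the class opacity corrected for the sampling
#' step (`1 - (1 - opacity)^step`, step in voxel units). Deterministic.
#'
#' @param volume a [SonoVolume-class].
#' @param labels a co-registered [LabelVolume-class].
#' @param tf a [TransferFunction-class].
#' @param camera a [Camera-class].
#' @return `height x width x 3` RGB array in \[0, 1\].
#' @export
raycast <- function(volume, labels, tf = TransferFunction(),
                    camera = Camera()) {
  stopifnot(is(volume, "SonoVolume"), is(labels, "LabelVolume"))
  if (!identical(dim(volume@voxels), dim(labels@labels)))
    stop("shape mismatch between volume and labels")
  vox <- volume@voxelMm
  d <- dim(volume@voxels)
  extent <- d * vox
  center <- extent / 2
  R <- sqrt(sum((extent / 2)^2))
  B <- .cameraBasis(camera)
  h <- camera@imageSize[1]; w <- camera@imageSize[2]
  # image-plane sample offsets (mm), symmetric about the volume centre
  us <- ((seq_len(w) - 0.5) / w - 0.5) * 2 * R
  vs <- ((seq_len(h) - 0.5) / h - 0.5) * 2 * R
  U <- rep(us, each = h)
  V <- rep(vs, times = w)
  origin <- cbind(center[1] + U * B$right[1] + V * B$up[1],
                  center[2] + U * B$right[2] + V * B$up[2],
                  center[3] + U * B$right[3] + V * B$up[3])
  stepMm <- camera@stepVoxels * min(vox)
  ts <- seq(-R, R, by = stepMm)
  n <- h * w
  accum <- matrix(0, n, 3)
  trans <- rep(1, n)
  colorsLut <- tf@colors
  opacityLut <- tf@opacity
  alphaLut <- 1 - (1 - opacityLut)^camera@stepVoxels  # step correction
  inten3d <- volume@voxels
  if (tf@intensityModulated && any(opacityLut == 0)) {
    # fully transparent classes (lumen by default) are blanked before
    # interpolation so their voxels never contribute, directly or by
    # intensity bleed into neighbouring samples
    zeroCls <- which(opacityLut == 0) - 1L
    inten3d[array(labels@labels %in% zeroCls, dim = d)] <- 0
  }
  for (t in ts) {
    live <- trans > 1e-4
    if (!any(live)) break
    pos <- origin[live, , drop = FALSE]
    pos[, 1] <- pos[, 1] + t * B$dir[1]
    pos[, 2] <- pos[, 2] + t * B$dir[2]
    pos[, 3] <- pos[, 3] + t * B$dir[3]
    f <- cbind(pos[, 1] / vox[1] + 0.5,
               pos[, 2] / vox[2] + 0.5,
               pos[, 3] / vox[3] + 0.5)
    cls <- .nearestLabel(labels@labels, f)
    hit <- cls > 0L | opacityLut[1] > 0
    if (!any(hit)) next
    alpha <- alphaLut[cls + 1L]
    colr <- colorsLut[cls + 1L, , drop = FALSE]
    if (tf@intensityModulated) {
      inten <- .trilinear(inten3d, f)
      colr <- colr * inten
    }
    idx <- which(live)
    wgt <- trans[idx] * alpha
    accum[idx, ] <- accum[idx, ] + colr * wgt
    trans[idx] <- trans[idx] * (1 - alpha)
  }
  accum <- accum + trans * matrix(tf@background, n, 3, byrow = TRUE)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- matrix(accum[, 1], h, w)
  img[, , 2] <- matrix(accum[, 2], h, w)
  img[, , 3] <- matrix(accum[, 3], h, w)
  img[img > 1] <- 1
  img
}

#' Render a set of views at multiple azimuth angles
#'
#' One raycast per requested azimuth; when `outDir` is given each image
#' is written as `view_az<angle>.png` (the filename encodes the angle).
#'
#' @param volume a [SonoVolume-class].
#' @param labels a co-registered [LabelVolume-class].
#' @param tf a [TransferFunction-class].
#' @param angles azimuth angles in degrees.
#' @param camera template [Camera-class]; its azimuth is replaced per
#'   view.
#' @param outDir optional output directory for PNG files.
#' @return named list of RGB arrays (`az0`, `az90`, ...).
#' @export
renderViews <- function(volume, labels, tf = TransferFunction(),
                        angles = c(0, 90, 180, 270), camera = Camera(),
                        outDir = NULL) {
  out <- vector("list", length(angles))
  names(out) <- paste0("az", angles)
  for (i in seq_along(angles)) {
    cam <- camera
    cam@azimuthDeg <- angles[i]
    out[[i]] <- raycast(volume, labels, tf, cam)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      png::writePNG(out[[i]],
                    file.path(outDir, sprintf("view_az%03d.png", round(angles[i]))))
    }
  }
  out
}

#' Read / write a TransferFunction as JSON
#'
#' @param tf a [TransferFunction-class].
#' @param path JSON file path.
#' @return `path` invisibly (write) or a [TransferFunction-class] (read).
#' @export
writeTransferFunction <- function(tf, path) {
  jsonlite::write_json(list(
    colors = apply(tf@colors, 1, identity, simplify = FALSE),
    opacity = tf@opacity,
    intensity_modulated = tf@intensityModulated,
    background = tf@background
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransferFunction
#' @export
readTransferFunction <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  colors <- if (is.matrix(j$colors)) j$colors else do.call(rbind, j$colors)
  TransferFunction(colors = colors,
                   opacity = as.numeric(j$opacity),
                   intensityModulated = isTRUE(j$intensity_modulated),
                   background = as.numeric(j$background))
}
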