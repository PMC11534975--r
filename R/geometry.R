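#' @include AllClasses.R
NULL

#' Frame count of a linear-motor sweep
#'
#' The number of frames collected during a constant-speed sweep is the
#' scan duration times the frame rate, rounded half away from zero (the
#' product is integral for typical settings, e.g. 21 s at 20 Hz gives
#' exactly 420 frames).
#'
#' @param scanTimeS scan duration in seconds, > 0.
#' @param frameRateHz frame rate in Hz, > 0.
#' @return integer frame count, >= 1.
#' @examples
#' computeFrameCount(21, 20)  # 420
#' @export
computeFrameCount <- function(scanTimeS, frameRateHz) {
  if (!is.numeric(scanTimeS) || length(scanTimeS) != 1L ||
      !is.finite(scanTimeS) || scanTimeS <= 0)
    stop("'scanTimeS' must be a single positive number")
  if (!is.numeric(frameRateHz) || length(frameRateHz) != 1L ||
      !is.finite(frameRateHz) || frameRateHz <= 0)
    stop("'frameRateHz' must be a single positive number")
  x <- scanTimeS * frameRateHz
  n <- as.integer(sign(x) * floor(abs(x) + 0.5))  # round half away from zero
  if (n < 1L) stop("geometry yields fewer than one frame")
  n
}

#' Elevational slice spacing of a sweep
#'
#' A probe travelling `travelMm` while collecting `frameCount` frames
#' samples elevational planes every `travelMm / frameCount` mm
#' (voxel-centre convention: frame k sits at `(k - 1) * spacing`, and the
#' reconstructed extent is `frameCount * spacing = travelMm`).
#'
#' @param travelMm probe translation in mm, > 0.
#' @param frameCount number of frames, >= 1.
#' @return slice spacing in mm.
#' @examples
#' computeSliceSpacing(35, 420)  # 0.0833 mm
#' @export
computeSliceSpacing <- function(travelMm, frameCount) {
  if (!is.numeric(travelMm) || length(travelMm) != 1L ||
      !is.finite(travelMm) || travelMm <= 0)
    stop("'travelMm' must be a single positive number")
  if (!is.numeric(frameCount) || length(frameCount) != 1L ||
      !is.finite(frameCount) || frameCount < 1)
    stop("'frameCount' must be an integer >= 1")
  travelMm / frameCount
}

#' Construct an AcquisitionGeometry
#'
#' @param travelMm probe translation (mm).
#' @param scanTimeS scan duration (s).
#' @param frameRateHz frame rate (Hz).
#' @param pixelMm in-plane pixel size `c(row, col)` in mm; a single value
#'   is used for both.
#' @return an [AcquisitionGeometry-class] object.
#' @examples
#' g <- AcquisitionGeometry(35, 21, 20, 0.1)
#' frameCount(g)
#' sliceSpacing(g)
#' @export
AcquisitionGeometry <- function(travelMm, scanTimeS, frameRateHz,
                                pixelMm = c(0.1, 0.1)) {
  if (length(pixelMm) == 1L) pixelMm <- rep(pixelMm, 2L)
  new("AcquisitionGeometry",
      travelMm = as.numeric(travelMm),
      scanTimeS = as.numeric(scanTimeS),
      frameRateHz = as.numeric(frameRateHz),
      pixelMm = as.numeric(pixelMm))
}

#' Construct a FrameStack
#'
#' @param frames list of identically shaped 2D matrices, or a 3D array
#'   (rows, cols, frames), intensities in \[0, 1\].
#' @param geometry an [AcquisitionGeometry-class]; its frame count must
#'   match the number of frames supplied.
#' @return a [FrameStack-class].
#' @export
FrameStack <- function(frames, geometry) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("empty stack: no frames supplied")
    d <- dim(frames[[1]])
    if (is.null(d) || length(d) != 2L) stop("frames must be 2D matrices")
    same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(same)) stop("shape mismatch: frames differ in shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  if (is.null(dim(frames)) || length(dim(frames)) != 3L)
    stop("'frames' must be a list of matrices or a 3D array")
  new("FrameStack", frames = frames, geometry = geometry)
}

#' Construct a SonoVolume
#'
#' @param voxels 3D intensity array in \[0, 1\].
#' @param voxelMm physical voxel size `c(row, col, slice)` in mm.
#' @return a [SonoVolume-class].
#' @export
SonoVolume <- function(voxels, voxelMm) {
  new("SonoVolume", voxels = voxels, voxelMm = as.numeric(voxelMm))
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer array with values in `{0, 1, 2, 3}`
#'   (see [tissueClasses()]).
#' @param voxelMm physical voxel size `c(row, col, slice)` in mm.
#' @return a [LabelVolume-class].
#' @export
LabelVolume <- function(labels, voxelMm) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, voxelMm = as.numeric(voxelMm))
}

#' Assemble a frame stack into a calibrated volume
#'
#' Frames are stacked unchanged along the elevational axis; the voxel
#' size is `(pixel row, pixel col, slice spacing)`. The operation is a
#' bijection: [disassembleVolume()] returns the original frames exactly.
#'
#' @param stack a [FrameStack-class].
#' @return a [SonoVolume-class].
#' @export
assembleVolume <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  g <- stack@geometry
  SonoVolume(stack@frames, c(g@pixelMm, sliceSpacing(g)))
}

#' Disassemble a volume back into its frames
#'
#' @param volume a [SonoVolume-class].
#' @return list of 2D matrices, one per slice, in acquisition order.
#' @export
disassembleVolume <- function(volume) {
  stopifnot(is(volume, "SonoVolume"))
  d <- dim(volume@voxels)
  lapply(seq_len(d[3]), function(k) volume@voxels[, , k])
}

#' Extract an axis-aligned plane (multiplanar reformation)
#'
#' The axial orientation is the acquisition plane: axial slice `k` is
#' frame `k`, returned exactly. Sagittal planes are orthogonal to the
#' probe face and contain the elevational axis (fixed column); coronal
#' planes fix a row. Re-slices carry the correct anisotropic pixel sizes.
#'
#' @param volume a [SonoVolume-class] or [LabelVolume-class].
#' @param orientation `"axial"`, `"sagittal"` or `"coronal"`.
#' @param index 1-based plane index along the fixed axis; alternatively
#'   give `offsetMm`, a physical offset converted to the nearest plane.
#' @param offsetMm optional physical position (mm) along the fixed axis.
#' @return list with elements `image` (2D matrix), `pixelMm` (length-2),
#'   `orientation` and `index`.
#' @export
extractPlane <- function(volume, orientation = c("axial", "sagittal", "coronal"),
                         index = NULL, offsetMm = NULL) {
  orientation <- match.arg(orientation)
  a <- if (is(volume, "LabelVolume")) volume@labels else volume@voxels
  vox <- voxelDims(volume)
  d <- dim(a)
  axis <- switch(orientation, axial = 3L, sagittal = 2L, coronal = 1L)
  if (is.null(index)) {
    if (is.null(offsetMm)) stop("give either 'index' or 'offsetMm'")
    index <- floor(offsetMm / vox[axis]) + 1L
  }
  if (index < 1L || index > d[axis])
    stop(sprintf("plane index %d out of bounds [1, %d]", index, d[axis]))
  switch(orientation,
    axial = list(image = a[, , index], pixelMm = vox[1:2],
                 orientation = orientation, index = as.integer(index)),
    sagittal = list(image = a[, index, ], pixelMm = vox[c(1, 3)],
                    orientation = orientation, index = as.integer(index)),
    coronal = list(image = a[index, , ], pixelMm = vox[c(2, 3)],
                   orientation = orientation, index = as.integer(index))
  )
}
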