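#' @include AllClasses.R
NULL

#' Number of frames implied by an acquisition geometry
#'
#' @param x an [AcquisitionGeometry-class] or [FrameStack-class].
#' @return integer frame count.
#' @seealso [computeFrameCount()]
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' Elevational slice spacing (mm)
#'
#' @param x an [AcquisitionGeometry-class] or [FrameStack-class].
#' @return slice spacing in mm.
#' @seealso [computeSliceSpacing()]
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' Voxel (or pixel) physical dimensions in mm
#'
#' @param x a [SonoVolume-class] or [LabelVolume-class].
#' @return numeric length-3, mm per voxel (row, col, slice).
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' Raw voxel intensities of a volume
#' @param x a [SonoVolume-class].
#' @return numeric 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Raw integer labels of a label volume
#' @param x a [LabelVolume-class].
#' @return integer 3D array.
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))

#' Frame data of a stack
#' @param x a [FrameStack-class].
#' @return numeric 3D array (rows, cols, frames).
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Acquisition geometry of a stack
#' @param x a [FrameStack-class].
#' @return an [AcquisitionGeometry-class].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

setMethod("frameCount", "AcquisitionGeometry", function(x) {
  computeFrameCount(x@scanTimeS, x@frameRateHz)
})
setMethod("frameCount", "FrameStack", function(x) dim(x@frames)[3])

setMethod("sliceSpacing", "AcquisitionGeometry", function(x) {
  computeSliceSpacing(x@travelMm, frameCount(x))
})
setMethod("sliceSpacing", "FrameStack", function(x) sliceSpacing(x@geometry))

setMethod("voxelDims", "SonoVolume", function(x) x@voxelMm)
setMethod("voxelDims", "LabelVolume", function(x) x@voxelMm)
setMethod("voxels", "SonoVolume", function(x) x@voxels)
setMethod("labels3d", "LabelVolume", function(x) x@labels)
setMethod("frames", "FrameStack", function(x) x@frames)
setMethod("geometry", "FrameStack", function(x) x@geometry)

setMethod("dim", "SonoVolume", function(x) dim(x@voxels))
setMethod("dim", "LabelVolume", function(x) dim(x@labels))
setMethod("dim", "FrameStack", function(x) dim(x@frames))

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry\n")
  cat(sprintf("  travel: %g mm over %g s at %g Hz\n",
              object@travelMm, object@scanTimeS, object@frameRateHz))
  cat(sprintf("  frames: %d, slice spacing %.4f mm\n",
              frameCount(object), sliceSpacing(object)))
  cat(sprintf("  in-plane pixel: %g x %g mm\n",
              object@pixelMm[1], object@pixelMm[2]))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d, spacing %.4f mm\n",
              d[3], d[1], d[2], sliceSpacing(object)))
})

setMethod("show", "SonoVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("SonoVolume: %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              object@voxelMm[1], object@voxelMm[2], object@voxelMm[3]))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(as.integer(object@labels), levels = .CLS))
  cat(sprintf("LabelVolume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat("  voxels per class:",
      paste(sprintf("%s=%d", names(.CLS), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "StrictureCurve", function(object) {
  cat(sprintf(
    "StrictureCurve: %d slices over %.2f mm, reference area %.3f mm^2\n",
    length(object@zMm), diff(range(object@zMm)) + object@sliceSpacingMm,
    object@referenceAreaMm2))
  cat(sprintf("  peak stricture ratio: %.1f%%\n", max(object@ratioPct)))
})

setMethod("show", "StrictureMeasurement", function(object) {
  if (object@lengthMm > 0) {
    cat(sprintf(
      "StrictureMeasurement: length %.2f mm (slices %d..%d), peak %.1f%% at threshold %.0f%%\n",
      object@lengthMm, object@extent[1], object@extent[2],
      object@maxRatioPct, object@thresholdPct))
  } else {
    cat(sprintf(
      "StrictureMeasurement: no stricture at threshold %.0f%% (peak %.1f%%)\n",
      object@thresholdPct, object@maxRatioPct))
  }
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d pairs)\n", object@n))
  cat(sprintf("  Spearman rho: %.3f\n", object@spearmanRho))
  cat(sprintf("  bias: %.3f mm, limits of agreement [%.3f, %.3f] mm\n",
              object@biasMm, object@loaLowerMm, object@loaUpperMm))
})

#' Convert a StrictureCurve to a data.frame
#'
#' @param x a [StrictureCurve-class].
#' @param row.names,optional,... passed through for the generic signature.
#' @return data.frame with columns `slice`, `z_mm`, `lumen_area_mm2`,
#'   `ratio_pct`.
#' @export
as.data.frame.StrictureCurve <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    slice = seq_along(x@zMm),
    z_mm = x@zMm,
    lumen_area_mm2 = x@lumenAreaMm2,
    ratio_pct = x@ratioPct
  )
}
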