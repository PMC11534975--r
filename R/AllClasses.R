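#' @import methods
NULL

#' Tissue class codes
#'
#' Fixed integer codes used throughout the package for the four tissue
#' classes of the segmentation: background/other tissue, urethral lumen,
#' corpus spongiosum and periurethral fibrosis.
#'
#' @return Named integer vector of length four.
#' @examples
#' tissueClasses()
#' @export
tissueClasses <- function() {
  c(background = 0L, lumen = 1L, spongiosum = 2L, fibrosis = 3L)
}

.CLS <- c(background = 0L, lumen = 1L, spongiosum = 2L, fibrosis = 3L)

#' AcquisitionGeometry: motor kinematics and pixel calibration
#'
#' Describes one linear-motor sweep of the ultrasound probe: total probe
#' translation (mm), scan duration (s), frame rate (Hz) and the in-plane
#' pixel size (mm, row then column). The frame count and the elevational
#' slice spacing are derived quantities, available through
#' [frameCount()] and [sliceSpacing()].
#'
#' @slot travelMm total probe translation along the elevational axis (mm).
#' @slot scanTimeS acquisition duration (s).
#' @slot frameRateHz frame rate (frames per second).
#' @slot pixelMm in-plane pixel size, `c(row, col)`, in mm.
#' @export
setClass("AcquisitionGeometry",
  representation(
    travelMm = "numeric",
    scanTimeS = "numeric",
    frameRateHz = "numeric",
    pixelMm = "numeric"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  for (s in c("travelMm", "scanTimeS", "frameRateHz")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single strictly positive number", s))
  }
  if (length(object@pixelMm) != 2L || any(!is.finite(object@pixelMm)) ||
      any(object@pixelMm <= 0))
    msg <- c(msg, "'pixelMm' must be two strictly positive numbers (row, col)")
  if (length(msg) == 0L &&
      computeFrameCount(object@scanTimeS, object@frameRateHz) < 1L)
    msg <- c(msg, "geometry yields a frame count below 1")
  if (length(msg)) msg else TRUE
})

#' FrameStack: an ordered stack of 2D grayscale frames
#'
#' Frames are stored as a `rows x cols x frames` array with intensities in
#' \[0, 1\]. Frame `k` sits at elevational position `(k - 1) * sliceSpacing`
#' (voxel-centre convention, first frame at 0).
#'
#' @slot frames numeric 3D array, values in \[0, 1\].
#' @slot geometry an [AcquisitionGeometry-class] object.
#' @export
setClass("FrameStack",
  representation(frames = "array", geometry = "AcquisitionGeometry")
)

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("'frames' must be a 3D array (rows, cols, frames)")
  if (any(d < 1L)) return("'frames' must be non-empty")
  rng <- range(object@frames)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    return("frame intensities must be finite and within [0, 1]")
  n <- frameCount(object@geometry)
  if (d[3] != n)
    return(sprintf("stack has %d frames but geometry implies %d", d[3], n))
  TRUE
})

#' SonoVolume: a calibrated grayscale 3D volume
#'
#' Voxels are stored as a `rows x cols x slices` array with intensities in
#' \[0, 1\]; `voxelMm` carries the physical voxel size (row, col, slice).
#' The slice size equals the elevational slice spacing of the source sweep.
#'
#' @slot voxels numeric 3D array in \[0, 1\].
#' @slot voxelMm numeric length-3, physical voxel size in mm.
#' @export
setClass("SonoVolume",
  representation(voxels = "array", voxelMm = "numeric")
)

.validVoxelGrid <- function(a, vox) {
  if (length(dim(a)) != 3L) return("voxel data must be a 3D array")
  if (length(vox) != 3L || any(!is.finite(vox)) || any(vox <= 0))
    return("'voxelMm' must be three strictly positive numbers")
  TRUE
}

setValidity("SonoVolume", function(object) {
  ok <- .validVoxelGrid(object@voxels, object@voxelMm)
  if (!isTRUE(ok)) return(ok)
  rng <- range(object@voxels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    return("voxel intensities must be finite and within [0, 1]")
  TRUE
})

#' LabelVolume: co-registered 4-class voxel labels
#'
#' Integer labels on the same grid as a [SonoVolume-class]; every voxel
#' holds exactly one of the four codes of [tissueClasses()].
#'
#' @slot labels integer 3D array with values in `{0, 1, 2, 3}`.
#' @slot voxelMm numeric length-3, physical voxel size in mm.
#' @export
setClass("LabelVolume",
  representation(labels = "array", voxelMm = "numeric")
)

setValidity("LabelVolume", function(object) {
  ok <- .validVoxelGrid(object@labels, object@voxelMm)
  if (!isTRUE(ok)) return(ok)
  u <- unique(as.integer(object@labels))
  if (!all(u %in% .CLS))
    return("labels must take values in {0, 1, 2, 3}")
  TRUE
})

#' PhantomSpec: parametric ground truth for a synthetic urethra
#'
#' Defines a water-distended urethral lumen (dark tube) inside a corpus
#' spongiosum sleeve (mid echogenicity), with an optional stricture
#' modelled as a raised-cosine narrowing of the lumen radius and
#' periurethral fibrosis foci (bright) within the spongiosum near the
#' stricture. Used by [generateLabels()] and [simulateFrames()].
#'
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot frameShape integer `c(rows, cols)` of each frame.
#' @slot lumenRadiusMm baseline lumen radius (mm).
#' @slot spongiosumRadiusMm outer corpus spongiosum radius (mm).
#' @slot strictureCenterMm elevational position of the stricture centre (mm).
#' @slot strictureLengthMm full width of the narrowed segment (mm); 0 for none.
#' @slot strictureDepth fractional radius reduction at the centre, in (0, 1].
#' @slot fibrosisPattern one of `"none"`, `"dotted"`, `"massive"`.
#' @slot fibrosisFraction target fraction of spongiosum voxels within the
#'   stricture zone that are marked fibrotic.
#' @slot echogenicity named numeric: mean intensity per class
#'   (`lumen`, `spongiosum`, `fibrosis`, `background`).
#' @slot speckleSigma multiplicative speckle scale (0 disables speckle).
#' @slot psfSigmaPx Gaussian point-spread blur width in pixels (0 disables).
#' @slot seed RNG seed making label and frame synthesis deterministic.
#' @export
setClass("PhantomSpec",
  representation(
    geometry = "AcquisitionGeometry",
    frameShape = "integer",
    lumenRadiusMm = "numeric",
    spongiosumRadiusMm = "numeric",
    strictureCenterMm = "numeric",
    strictureLengthMm = "numeric",
    strictureDepth = "numeric",
    fibrosisPattern = "character",
    fibrosisFraction = "numeric",
    echogenicity = "numeric",
    speckleSigma = "numeric",
    psfSigmaPx = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@frameShape) != 2L || any(object@frameShape < 8L))
    msg <- c(msg, "'frameShape' must be two integers >= 8")
  if (!(object@lumenRadiusMm > 0 &&
        object@lumenRadiusMm < object@spongiosumRadiusMm))
    msg <- c(msg, "need 0 < lumenRadiusMm < spongiosumRadiusMm")
  if (object@strictureLengthMm < 0)
    msg <- c(msg, "'strictureLengthMm' must be >= 0")
  if (object@strictureLengthMm > 0) {
    if (!(object@strictureDepth > 0 && object@strictureDepth <= 1))
      msg <- c(msg, "'strictureDepth' must lie in (0, 1]")
    lo <- object@strictureCenterMm - object@strictureLengthMm / 2
    hi <- object@strictureCenterMm + object@strictureLengthMm / 2
    if (lo < 0 || hi > object@geometry@travelMm)
      msg <- c(msg, "stricture segment must lie inside the scanned extent")
  }
  if (!object@fibrosisPattern %in% c("none", "dotted", "massive"))
    msg <- c(msg, "'fibrosisPattern' must be none, dotted or massive")
  if (object@fibrosisFraction < 0 || object@fibrosisFraction >= 1)
    msg <- c(msg, "'fibrosisFraction' must lie in [0, 1)")
  ec <- object@echogenicity
  need <- c("lumen", "spongiosum", "fibrosis", "background")
  if (!all(need %in% names(ec))) {
    msg <- c(msg, "'echogenicity' must name lumen, spongiosum, fibrosis, background")
  } else if (!(ec["lumen"] < ec["spongiosum"] && ec["spongiosum"] < ec["fibrosis"])) {
    msg <- c(msg, "echogenicity must satisfy lumen < spongiosum < fibrosis")
  } else if (any(ec < 0 | ec > 1)) {
    msg <- c(msg, "echogenicity values must lie in [0, 1]")
  }
  if (object@speckleSigma < 0) msg <- c(msg, "'speckleSigma' must be >= 0")
  if (object@psfSigmaPx < 0) msg <- c(msg, "'psfSigmaPx' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StrictureCurve: the stricture ratio along the urethra
#'
#' Per-slice elevational position, lumen cross-sectional area and the
#' stricture ratio (%), defined as
#' `(reference area - slice area) / reference area * 100`, clipped below
#' at 0 when a slice exceeds the reference. See [strictureRatioCurve()].
#'
#' @slot zMm per-slice elevational position (mm), strictly increasing.
#' @slot lumenAreaMm2 per-slice lumen cross-sectional area (mm^2).
#' @slot ratioPct per-slice stricture ratio, in \[0, 100\].
#' @slot referenceAreaMm2 the reference lumen area used (mm^2).
#' @slot sliceSpacingMm elevational sampling interval (mm).
#' @export
setClass("StrictureCurve",
  representation(
    zMm = "numeric",
    lumenAreaMm2 = "numeric",
    ratioPct = "numeric",
    referenceAreaMm2 = "numeric",
    sliceSpacingMm = "numeric"
  )
)

setValidity("StrictureCurve", function(object) {
  n <- length(object@zMm)
  if (length(object@lumenAreaMm2) != n || length(object@ratioPct) != n)
    return("zMm, lumenAreaMm2 and ratioPct must have equal length")
  if (n > 1 && any(diff(object@zMm) <= 0))
    return("zMm must be strictly increasing")
  if (any(object@ratioPct < 0 | object@ratioPct > 100))
    return("ratioPct must lie in [0, 100]")
  if (object@referenceAreaMm2 <= 0)
    return("referenceAreaMm2 must be > 0")
  TRUE
})

#' StrictureMeasurement: detected stricture extent and physical length
#'
#' Result of thresholding a [StrictureCurve-class]: the longest contiguous
#' run of slices at or above the detection threshold, its physical length
#' (run slice count times slice spacing), the peak ratio, and all
#' supra-threshold runs as secondary findings.
#'
#' @slot lengthMm physical stricture length (mm); 0 when none detected.
#' @slot extent integer `c(first, last)` slice index of the detected run
#'   (1-based), or `integer(0)` when none.
#' @slot maxRatioPct peak stricture ratio over the curve.
#' @slot thresholdPct detection cutoff used (%).
#' @slot referenceAreaMm2 reference lumen area used (mm^2).
#' @slot runs data.frame of all supra-threshold runs
#'   (`first`, `last`, `lengthMm`).
#' @export
setClass("StrictureMeasurement",
  representation(
    lengthMm = "numeric",
    extent = "integer",
    maxRatioPct = "numeric",
    thresholdPct = "numeric",
    referenceAreaMm2 = "numeric",
    runs = "data.frame"
  )
)

setValidity("StrictureMeasurement", function(object) {
  if (!length(object@extent) %in% c(0L, 2L))
    return("'extent' must be empty or c(first, last)")
  if (object@lengthMm > 0 && object@maxRatioPct < object@thresholdPct)
    return("maxRatioPct must be >= thresholdPct when a stricture is detected")
  TRUE
})

#' TransferFunction: class-based colours and opacities for rendering
#'
#' Maps each tissue class to an RGB colour and an opacity (per unit voxel
#' of ray travel). The urethral lumen is fully transparent by default,
#' which removes reflection/reverberation artefacts from the rendering;
#' fibrosis gets a colour and opacity distinct from every other class.
#'
#' @slot colors 4 x 3 numeric matrix, rows in class-code order 0..3,
#'   RGB in \[0, 1\].
#' @slot opacity numeric length-4 in \[0, 1\], class-code order 0..3.
#' @slot intensityModulated logical; if `TRUE` sample colour is scaled by
#'   the interpolated voxel intensity.
#' @slot background RGB background colour.
#' @export
setClass("TransferFunction",
  representation(
    colors = "matrix",
    opacity = "numeric",
    intensityModulated = "logical",
    background = "numeric"
  )
)

setValidity("TransferFunction", function(object) {
  if (!all(dim(object@colors) == c(4L, 3L)))
    return("'colors' must be a 4 x 3 matrix (classes 0..3 x RGB)")
  if (any(object@colors < 0 | object@colors > 1))
    return("colours must lie in [0, 1]")
  if (length(object@opacity) != 4L ||
      any(object@opacity < 0 | object@opacity > 1))
    return("'opacity' must be four values in [0, 1]")
  if (length(object@background) != 3L)
    return("'background' must be an RGB triple")
  TRUE
})

#' Camera: orthographic view for raycasting
#'
#' @slot azimuthDeg rotation about the elevational (slice) axis, degrees.
#' @slot elevationDeg tilt of the view direction towards the slice axis,
#'   degrees.
#' @slot imageSize integer `c(height, width)` of the rendered image.
#' @slot stepVoxels ray sampling step, in units of the smallest voxel
#'   dimension; must lie in (0, 1].
#' @export
setClass("Camera",
  representation(
    azimuthDeg = "numeric",
    elevationDeg = "numeric",
    imageSize = "integer",
    stepVoxels = "numeric"
  )
)

setValidity("Camera", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 4L))
    return("'imageSize' must be two integers >= 4")
  if (object@stepVoxels <= 0 || object@stepVoxels > 1)
    return("'stepVoxels' must lie in (0, 1]")
  TRUE
})

#' AgreementReport: method-agreement statistics for paired lengths
#'
#' Holds the Spearman rank correlation and Bland-Altman summary (bias,
#' SD of differences, limits of agreement) for paired stricture-length
#' measurements from two methods.
#'
#' @slot spearmanRho Spearman rank correlation.
#' @slot biasMm mean difference a - b (mm).
#' @slot sdMm sample SD of the differences (mm).
#' @slot loaLowerMm lower limit of agreement (mm).
#' @slot loaUpperMm upper limit of agreement (mm).
#' @slot limitMultiplier the multiplier applied to the SD (1.96 default).
#' @slot n number of complete pairs used.
#' @slot pairs data.frame with columns `a`, `b`, `mean`, `diff`.
#' @export
setClass("AgreementReport",
  representation(
    spearmanRho = "numeric",
    biasMm = "numeric",
    sdMm = "numeric",
    loaLowerMm = "numeric",
    loaUpperMm = "numeric",
    limitMultiplier = "numeric",
    n = "integer",
    pairs = "data.frame"
  )
)

setValidity("AgreementReport", function(object) {
  if (length(object@spearmanRho) == 1L && is.finite(object@spearmanRho) &&
      abs(object@spearmanRho) > 1 + 1e-12)
    return("|spearmanRho| must be <= 1")
  if (is.finite(object@biasMm) &&
      (object@loaLowerMm > object@biasMm || object@biasMm > object@loaUpperMm))
    return("limits of agreement must bracket the bias")
  TRUE
})
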