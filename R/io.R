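#' @include AllClasses.R geometry.R
NULL

.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Write a volume or label volume to NIfTI
#'
#' Grayscale volumes are stored as float64 (round-trip within numerical
#' identity), label volumes as int16. Voxel sizes go into the NIfTI
#' pixdim header fields.
#'
#' @param volume a [SonoVolume-class] or [LabelVolume-class].
#' @param path destination, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  if (!.isNifti(path)) stop("unrecognized volume format (use .nii/.nii.gz): ", path)
  if (is(volume, "LabelVolume")) {
    a <- volume@labels
    dt <- "int16"
  } else if (is(volume, "SonoVolume")) {
    a <- volume@voxels
    dt <- "double"
  } else stop("'volume' must be a SonoVolume or LabelVolume")
  attr(a, "pixdim") <- voxelDims(volume)
  RNifti::writeNifti(RNifti::asNifti(a), path, datatype = dt)
  invisible(path)
}

#' Read a grayscale volume from NIfTI
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a [SonoVolume-class] with voxel sizes taken from the header.
#' @export
readVolume <- function(path) {
  if (!.isNifti(path)) stop("unrecognized volume format (use .nii/.nii.gz): ", path)
  img <- RNifti::readNifti(path)
  SonoVolume(array(as.numeric(img), dim = dim(img)),
             RNifti::pixdim(img)[1:3])
}

#' Read a label volume from NIfTI
#'
#' @param path a `.nii` or `.nii.gz` file holding integer class codes.
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path) {
  if (!.isNifti(path)) stop("unrecognized volume format (use .nii/.nii.gz): ", path)
  img <- RNifti::readNifti(path)
  LabelVolume(array(as.integer(round(as.numeric(img))), dim = dim(img)),
              RNifti::pixdim(img)[1:3])
}

.writeGeometryJson <- function(geometry, path) {
  jsonlite::write_json(
    list(travel_mm = geometry@travelMm,
         scan_time_s = geometry@scanTimeS,
         frame_rate_hz = geometry@frameRateHz,
         pixel_mm = geometry@pixelMm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.readGeometryJson <- function(path) {
  if (!file.exists(path))
    stop("missing geometry sidecar: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("travel_mm", "scan_time_s", "frame_rate_hz", "pixel_mm")
  if (!all(need %in% names(j)))
    stop("geometry sidecar must contain keys: ", paste(need, collapse = ", "))
  AcquisitionGeometry(j$travel_mm, j$scan_time_s, j$frame_rate_hz,
                      as.numeric(j$pixel_mm))
}

#' Write a frame stack to disk
#'
#' Two layouts are supported: a multipage 16-bit TIFF (`path` ends in
#' `.tif`/`.tiff`; intensities are denormalized onto the 16-bit integer
#' grid, so values of the form k/65535 round-trip exactly), or a
#' directory of numbered 8-bit PNG frames. In both cases the acquisition
#' geometry is written to a `geometry.json` sidecar (next to the TIFF,
#' or inside the directory).
#'
#' @param stack a [FrameStack-class].
#' @param path a `.tif`/`.tiff` file or a directory.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@frames)
  if (.isTiff(path)) {
    pages <- lapply(seq_len(d[3]), function(k) stack@frames[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    .writeGeometryJson(stack@geometry,
                       file.path(dirname(path), "geometry.json"))
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_len(d[3]))
      png::writePNG(stack@frames[, , k],
                    file.path(path, sprintf("frame_%04d.png", k)))
    .writeGeometryJson(stack@geometry, file.path(path, "geometry.json"))
  }
  invisible(path)
}

#' Read a frame stack from disk
#'
#' Accepts the layouts written by [writeStack()]: a multipage TIFF with a
#' `geometry.json` sidecar next to it, or a directory of PNG frames
#' (sorted by filename) containing `geometry.json`. Integer intensities
#' are normalized to \[0, 1\] on read.
#'
#' @param path a `.tif`/`.tiff` file or a directory.
#' @return a [FrameStack-class].
#' @export
readStack <- function(path) {
  if (.isTiff(path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    geometry <- .readGeometryJson(file.path(dirname(path), "geometry.json"))
  } else if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("empty stack: no PNG frames in ", path)
    pages <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3L) im <- im[, , 1]  # grayscale channel
      im
    })
    geometry <- .readGeometryJson(file.path(path, "geometry.json"))
  } else {
    stop("unrecognized stack source (TIFF file or PNG directory): ", path)
  }
  FrameStack(pages, geometry)
}
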