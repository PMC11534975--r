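#' @include AllClasses.R
NULL

#' Per-slice lumen cross-sectional area
#'
#' `area_k = (# lumen-coded voxels in slice k) * rowMm * colMm`.
#'
#' @param labels a [LabelVolume-class].
#' @return numeric vector of areas in mm^2, one per slice.
#' @export
lumenAreaPerSlice <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  pxArea <- prod(labels@voxelMm[1:2])
  apply(labels@labels == .CLS[["lumen"]], 3, sum) * pxArea
}

#' Reference urethral lumen area
#'
#' The stricture ratio needs a reference ("healthy") lumen area; the rule
#' is configurable because no single convention exists. The default is
#' the 90th percentile of the per-slice areas, which is robust as long as
#' the stricture leaves a reasonable fraction of the sweep near baseline
#' calibre. Alternatives: `median`, `max`, or a `fixed` value in mm^2.
#'
#' @param areas per-slice lumen areas (mm^2).
#' @param method `"p90"`, `"median"`, `"max"` or `"fixed"`.
#' @param fixedValue reference area in mm^2 when `method = "fixed"`.
#' @return reference area in mm^2.
#' @export
referenceArea <- function(areas, method = c("p90", "median", "max", "fixed"),
                          fixedValue = NULL) {
  method <- match.arg(method)
  if (method != "fixed" && !any(areas > 0))
    stop("degenerate anatomy: all per-slice lumen areas are zero")
  switch(method,
    p90 = unname(stats::quantile(areas, 0.9, type = 7)),
    median = stats::median(areas),
    max = max(areas),
    fixed = {
      if (is.null(fixedValue) || fixedValue <= 0)
        stop("'fixedValue' must be a positive area for method = \"fixed\"")
      fixedValue
    })
}

#' Stricture ratio of a single slice
#'
#' `(reference area - slice area) / reference area * 100`, clipped below
#' at 0 when the slice area exceeds the reference.
#'
#' @param referenceAreaMm2 reference lumen area (mm^2), > 0.
#' @param areaMm2 slice lumen area (mm^2).
#' @return ratio in \[0, 100\].
#' @examples
#' strictureRatio(80, 20)  # 75
#' @export
strictureRatio <- function(referenceAreaMm2, areaMm2) {
  if (referenceAreaMm2 <= 0) stop("reference area must be > 0")
  pmin(100, pmax(0, (referenceAreaMm2 - areaMm2) / referenceAreaMm2 * 100))
}

#' Stricture-ratio curve along the urethra
#'
#' Computes the per-slice lumen area, picks the reference area by the
#' requested rule and evaluates the stricture ratio at every elevational
#' position (`z_k = (k - 1) * slice spacing`).
#'
#' @param labels a [LabelVolume-class].
#' @param referenceMethod passed to [referenceArea()].
#' @param fixedValue reference area when `referenceMethod = "fixed"`.
#' @return a [StrictureCurve-class].
#' @export
strictureRatioCurve <- function(labels, referenceMethod = "p90",
                                fixedValue = NULL) {
  areas <- lumenAreaPerSlice(labels)
  ref <- referenceArea(areas, method = referenceMethod, fixedValue = fixedValue)
  spacing <- labels@voxelMm[3]
  new("StrictureCurve",
      zMm = (seq_along(areas) - 1) * spacing,
      lumenAreaMm2 = areas,
      ratioPct = strictureRatio(ref, areas),
      referenceAreaMm2 = ref,
      sliceSpacingMm = spacing)
}

#' Measure the physical stricture length from a stricture curve
#'
#' The detected extent is the longest contiguous run of slices whose
#' ratio is at or above the threshold (ties broken towards the first
#' run); its physical length is the run slice count times the slice
#' spacing, consistent with a total reconstructed extent of
#' `frameCount * spacing`. All supra-threshold runs are reported as
#' secondary findings in `@runs`.
#'
#' @param curve a [StrictureCurve-class].
#' @param thresholdPct detection cutoff in (0, 100); default 50 (a
#'   half-calibre landmark, always reported alongside the result).
#' @return a [StrictureMeasurement-class].
#' @export
measureStrictureLength <- function(curve, thresholdPct = 50) {
  stopifnot(is(curve, "StrictureCurve"))
  if (thresholdPct <= 0 || thresholdPct >= 100)
    stop("'thresholdPct' must lie strictly between 0 and 100")
  spacing <- curve@sliceSpacingMm
  above <- curve@ratioPct >= thresholdPct
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  runs <- data.frame(first = starts[keep], last = ends[keep],
                     lengthMm = r$lengths[keep] * spacing)
  if (nrow(runs) == 0L) {
    return(new("StrictureMeasurement",
               lengthMm = 0, extent = integer(0),
               maxRatioPct = max(curve@ratioPct),
               thresholdPct = thresholdPct,
               referenceAreaMm2 = curve@referenceAreaMm2,
               runs = runs))
  }
  best <- which.max(runs$lengthMm)  # ties -> first run
  new("StrictureMeasurement",
      lengthMm = runs$lengthMm[best],
      extent = as.integer(c(runs$first[best], runs$last[best])),
      maxRatioPct = max(curve@ratioPct),
      thresholdPct = thresholdPct,
      referenceAreaMm2 = curve@referenceAreaMm2,
      runs = runs)
}

#' Write a stricture curve and measurement report
#'
#' @param curve a [StrictureCurve-class].
#' @param measurement a [StrictureMeasurement-class].
#' @param curveCsv optional path for the per-slice curve CSV
#'   (columns slice, z_mm, lumen_area_mm2, ratio_pct).
#' @param reportJson optional path for the JSON measurement report.
#' @return invisibly, a list with the report fields.
#' @export
writeStrictureReport <- function(curve, measurement, curveCsv = NULL,
                                 reportJson = NULL) {
  if (!is.null(curveCsv))
    utils::write.csv(as.data.frame(curve), curveCsv, row.names = FALSE)
  rep <- list(
    length_mm = measurement@lengthMm,
    extent = if (length(measurement@extent)) measurement@extent else NULL,
    max_ratio_pct = measurement@maxRatioPct,
    threshold_pct = measurement@thresholdPct,
    reference_area_mm2 = measurement@referenceAreaMm2,
    runs = measurement@runs
  )
  if (!is.null(reportJson))
    jsonlite::write_json(rep, reportJson, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(rep)
}
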