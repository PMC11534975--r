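#' @include AllClasses.R geometry.R
NULL

# Run code with a private RNG state so synthesis is deterministic given a
# seed and never disturbs the caller's stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a PhantomSpec
#'
#' Defaults describe the acquisition conditions of the motorized sweep
#' (35 mm travel, 21 s at 20 Hz, hence 420 frames at 0.0833 mm spacing)
#' and an anatomy-scale urethra: 2 mm baseline lumen radius inside a 5 mm
#' corpus spongiosum, a 14 mm stricture of depth 0.8 centred mid-sweep,
#' and dotted fibrosis occupying 15% of the spongiosum near the
#' stricture. Echogenicity defaults (dark water-filled lumen, mid-gray
#' spongiosum, bright scar) are a synthetic convention chosen for class
#' separability, not a measured tissue property.
#'
#' @param geometry an [AcquisitionGeometry-class].
#' @param frameShape `c(rows, cols)` of each frame.
#' @param lumenRadiusMm,spongiosumRadiusMm tube radii in mm.
#' @param strictureCenterMm,strictureLengthMm,strictureDepth raised-cosine
#'   stricture: centre (mm), full width (mm, 0 disables), fractional
#'   radius reduction at centre in (0, 1].
#' @param fibrosisPattern `"none"`, `"dotted"` (small spheres) or
#'   `"massive"` (one contiguous blob).
#' @param fibrosisFraction target fraction of stricture-zone spongiosum
#'   voxels marked fibrotic.
#' @param echogenicity named mean intensities per class.
#' @param speckleSigma multiplicative speckle scale (Gamma, unit mean).
#' @param psfSigmaPx Gaussian point-spread blur width in pixels.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(geometry = AcquisitionGeometry(35, 7, 10, 0.15),
#'                     frameShape = c(96, 96))
#' @export
PhantomSpec <- function(geometry = AcquisitionGeometry(35, 21, 20, c(0.1, 0.1)),
                        frameShape = c(128L, 128L),
                        lumenRadiusMm = 2,
                        spongiosumRadiusMm = 5,
                        strictureCenterMm = geometry@travelMm / 2,
                        strictureLengthMm = 14,
                        strictureDepth = 0.8,
                        fibrosisPattern = c("dotted", "massive", "none"),
                        fibrosisFraction = 0.15,
                        echogenicity = c(lumen = 0.05, spongiosum = 0.55,
                                         fibrosis = 0.95, background = 0.2),
                        speckleSigma = 0.3,
                        psfSigmaPx = 1,
                        seed = 0L) {
  fibrosisPattern <- match.arg(fibrosisPattern)
  if (strictureLengthMm == 0) fibrosisPattern <- "none"
  new("PhantomSpec",
      geometry = geometry,
      frameShape = as.integer(frameShape),
      lumenRadiusMm = as.numeric(lumenRadiusMm),
      spongiosumRadiusMm = as.numeric(spongiosumRadiusMm),
      strictureCenterMm = as.numeric(strictureCenterMm),
      strictureLengthMm = as.numeric(strictureLengthMm),
      strictureDepth = as.numeric(strictureDepth),
      fibrosisPattern = fibrosisPattern,
      fibrosisFraction = as.numeric(fibrosisFraction),
      echogenicity = echogenicity,
      speckleSigma = as.numeric(speckleSigma),
      psfSigmaPx = as.numeric(psfSigmaPx),
      seed = as.integer(seed))
}

# Raised-cosine stricture window: 1 at the centre, 0 outside the segment.
.strictureWindow <- function(z, centerMm, lengthMm) {
  if (lengthMm <= 0) return(numeric(length(z)))
  u <- (z - centerMm) / lengthMm
  w <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  w
}

#' Lumen radius profile of a phantom
#'
#' `r(z) = lumenRadius * (1 - depth * w(z))` with `w` a raised-cosine
#' window of full width `strictureLengthMm` centred at
#' `strictureCenterMm`.
#'
#' @param spec a [PhantomSpec-class].
#' @param zMm elevational positions (mm).
#' @return lumen radius (mm) at each position.
#' @export
lumenRadiusProfile <- function(spec, zMm) {
  w <- .strictureWindow(zMm, spec@strictureCenterMm, spec@strictureLengthMm)
  spec@lumenRadiusMm * (1 - spec@strictureDepth * w)
}

#' Analytic supra-threshold stricture span
#'
#' Closed-form physical span over which the ground-truth stricture ratio
#' (relative to the baseline lumen area) is at least `thresholdPct`.
#' Since area scales as radius squared, the ratio at position z is
#' `(1 - (1 - depth * w(z))^2) * 100`; inverting the raised cosine gives
#' the span `L / pi * acos(2 * wReq - 1)` where
#' `wReq = (1 - sqrt(1 - threshold/100)) / depth`.
#'
#' @param spec a [PhantomSpec-class].
#' @param thresholdPct ratio cutoff in (0, 100).
#' @return span in mm (0 when the stricture never reaches the threshold).
#' @export
analyticStrictureSpan <- function(spec, thresholdPct = 50) {
  if (spec@strictureLengthMm <= 0) return(0)
  wReq <- (1 - sqrt(1 - thresholdPct / 100)) / spec@strictureDepth
  if (wReq > 1) return(0)
  spec@strictureLengthMm / pi * acos(2 * wReq - 1)
}

# In-plane distance (mm) of every pixel centre from the frame centre.
.radialMap <- function(frameShape, pixelMm) {
  dr <- ((seq_len(frameShape[1]) - 0.5) - frameShape[1] / 2) * pixelMm[1]
  dc <- ((seq_len(frameShape[2]) - 0.5) - frameShape[2] / 2) * pixelMm[2]
  sqrt(outer(dr^2, dc^2, "+"))
}

#' Generate the ground-truth label volume of a phantom
#'
#' Builds the 4-class voxel labels: a lumen tube whose radius follows the
#' raised-cosine stricture profile, a corpus spongiosum annulus, and
#' fibrosis foci carved inside the spongiosum within the stricture zone
#' ("dotted": Poisson-disc-sampled spheres of 2-4 voxel radius;
#' "massive": one contiguous ellipsoid sized by bisection to the target
#' fraction). Deterministic given `spec@seed`.
#'
#' @param spec a valid [PhantomSpec-class].
#' @return a [LabelVolume-class].
#' @export
generateLabels <- function(spec) {
  validObject(spec)
  g <- spec@geometry
  n <- frameCount(g)
  spacing <- sliceSpacing(g)
  z <- (seq_len(n) - 1) * spacing
  rho <- .radialMap(spec@frameShape, g@pixelMm)
  rz <- lumenRadiusProfile(spec, z)
  spong <- rho <= spec@spongiosumRadiusMm
  labels <- array(0L, dim = c(spec@frameShape, n))
  for (k in seq_len(n)) {
    sl <- ifelse(spong, .CLS[["spongiosum"]], .CLS[["background"]])
    sl[rho <= rz[k]] <- .CLS[["lumen"]]
    labels[, , k] <- sl
  }
  if (spec@fibrosisPattern != "none" && spec@fibrosisFraction > 0)
    labels <- .withSeed(spec@seed, .addFibrosis(labels, spec, z, rho))
  LabelVolume(labels, c(g@pixelMm, spacing))
}

.addFibrosis <- function(labels, spec, z, rho) {
  inZone <- abs(z - spec@strictureCenterMm) <= spec@strictureLengthMm / 2
  zoneK <- which(inZone)
  if (length(zoneK) == 0L) return(labels)
  annulus <- labels[, , zoneK, drop = FALSE] == .CLS[["spongiosum"]]
  target <- round(spec@fibrosisFraction * sum(annulus))
  if (target < 1L) return(labels)
  d <- dim(labels)
  if (spec@fibrosisPattern == "dotted") {
    placed <- matrix(numeric(0), ncol = 4)  # i, j, k, radius
    got <- 0L
    for (attempt in seq_len(5000L)) {
      if (got >= target) break
      k <- sample(zoneK, 1L)
      cand <- which(labels[, , k] == .CLS[["spongiosum"]])
      if (length(cand) == 0L) next
      p <- cand[sample.int(length(cand), 1L)]
      i <- (p - 1L) %% d[1] + 1L
      j <- (p - 1L) %/% d[1] + 1L
      r <- stats::runif(1, 2, 4)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - i)^2 + (placed[, 2] - j)^2 +
                     (placed[, 3] - k)^2)
        if (any(dd < placed[, 4] + r + 1)) next  # Poisson-disc spacing
      }
      added <- .carveBlob(labels, c(i, j, k), c(r, r, r), zoneK)
      labels <- added$labels
      got <- got + added$count
      placed <- rbind(placed, c(i, j, k, r))
    }
  } else {  # massive: one contiguous ellipsoid, sized by bisection
    kc <- zoneK[which.min(abs(z[zoneK] - spec@strictureCenterMm))]
    cand <- which(labels[, , kc] == .CLS[["spongiosum"]])
    p <- cand[sample.int(length(cand), 1L)]
    i <- (p - 1L) %% d[1] + 1L
    j <- (p - 1L) %/% d[1] + 1L
    ar <- max(3, (spec@spongiosumRadiusMm - spec@lumenRadiusMm) /
                spec@geometry@pixelMm[1])
    az <- max(3, length(zoneK) / 2)
    lo <- 0.02; hi <- 4
    for (it in seq_len(24L)) {
      mid <- (lo + hi) / 2
      cnt <- .carveBlob(labels, c(i, j, kc), mid * c(ar, ar, az), zoneK,
                        dryRun = TRUE)$count
      if (cnt < target) lo <- mid else hi <- mid
    }
    labels <- .carveBlob(labels, c(i, j, kc), hi * c(ar, ar, az), zoneK)$labels
  }
  labels
}

# Mark spongiosum voxels inside an axis-aligned ellipsoid (voxel units)
# as fibrosis, restricted to the stricture-zone slices.
.carveBlob <- function(labels, center, semiAxes, zoneK, dryRun = FALSE) {
  d <- dim(labels)
  ir <- max(1L, floor(center[1] - semiAxes[1])):min(d[1], ceiling(center[1] + semiAxes[1]))
  jr <- max(1L, floor(center[2] - semiAxes[2])):min(d[2], ceiling(center[2] + semiAxes[2]))
  kr <- intersect(max(1L, floor(center[3] - semiAxes[3])):min(d[3], ceiling(center[3] + semiAxes[3])),
                  zoneK)
  if (length(kr) == 0L) return(list(labels = labels, count = 0L))
  di <- (ir - center[1]) / semiAxes[1]
  dj <- (jr - center[2]) / semiAxes[2]
  dk <- (kr - center[3]) / semiAxes[3]
  inside <- outer(outer(di^2, dj^2, "+"), dk^2, "+") <= 1
  sub <- labels[ir, jr, kr, drop = FALSE]
  hit <- inside & (sub == .CLS[["spongiosum"]])
  if (!dryRun && any(hit)) {
    sub[hit] <- .CLS[["fibrosis"]]
    labels[ir, jr, kr] <- sub
  }
  list(labels = labels, count = sum(hit))
}

#' Simulate B-mode-like frames from a label volume
#'
#' Each voxel takes its class mean echogenicity, each frame is blurred by
#' a Gaussian point-spread function of width `psfSigmaPx`, and the result
#' is multiplied by i.i.d. unit-mean Gamma speckle
#' (`shape = 1/speckleSigma^2`, `scale = speckleSigma^2`) and clipped to
#' \[0, 1\]. With `speckleSigma = 0` and `psfSigmaPx = 0` the frames are
#' exact class-intensity maps. Deterministic given `spec@seed`.
#'
#' @param labels the [LabelVolume-class] generated from `spec`.
#' @param spec the [PhantomSpec-class].
#' @return a [FrameStack-class].
#' @export
simulateFrames <- function(labels, spec) {
  stopifnot(is(labels, "LabelVolume"))
  ec <- spec@echogenicity
  lut <- c(ec[["background"]], ec[["lumen"]], ec[["spongiosum"]], ec[["fibrosis"]])
  d <- dim(labels@labels)
  vol <- array(lut[labels@labels + 1L], dim = d)
  if (spec@psfSigmaPx > 0) {
    for (k in seq_len(d[3]))
      vol[, , k] <- EBImage::gblur(vol[, , k], sigma = spec@psfSigmaPx)
  }
  if (spec@speckleSigma > 0) {
    s2 <- spec@speckleSigma^2
    speckle <- .withSeed(spec@seed + 1L,
                         stats::rgamma(length(vol), shape = 1 / s2, scale = s2))
    vol <- vol * array(speckle, dim = d)
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  FrameStack(vol, spec@geometry)
}

#' Ground-truth stricture measurement from perfect labels
#'
#' Runs the same stricture-curve and length logic as the measurement
#' pipeline ([strictureRatioCurve()], [measureStrictureLength()]) on the
#' ground-truth labels; used as the recovery target when evaluating
#' segmentation backends.
#'
#' @param labels a [LabelVolume-class].
#' @param thresholdPct detection cutoff (%).
#' @param referenceMethod reference-area rule, see [referenceArea()].
#' @return a [StrictureMeasurement-class].
#' @export
groundTruthMeasurement <- function(labels, thresholdPct = 50,
                                   referenceMethod = "p90") {
  if (!any(labels@labels == .CLS[["lumen"]]))
    stop("degenerate anatomy: no lumen voxels anywhere")
  curve <- strictureRatioCurve(labels, referenceMethod = referenceMethod)
  measureStrictureLength(curve, thresholdPct = thresholdPct)
}

#' End-to-end stricture-length recovery experiment
#'
#' Generates a family of seeded phantoms spanning a range of stricture
#' lengths and depths, runs the full measurement pipeline on each
#' (simulate frames, segment with the requested backend, build the
#' stricture curve, measure the length) and tabulates the measured
#' length against the ground-truth measurement from the perfect labels.
#' The default problem size (96 x 96 frames at 0.15 mm, 140 slices over
#' a 35 mm sweep) keeps a 20-phantom run at desk scale.
#'
#' @param nPhantoms number of phantoms.
#' @param lengthsMm stricture lengths to span (recycled over phantoms).
#' @param depths stricture depths to span (recycled).
#' @param seed base RNG seed; phantom i uses `seed + i`.
#' @param speckleSigma,psfSigmaPx noise settings (default noiseless).
#' @param backend segmentation backend passed to [segmentStack()].
#' @param thresholdPct,referenceMethod measurement settings.
#' @param geometry,frameShape,lumenRadiusMm,spongiosumRadiusMm anatomy
#'   and sweep settings shared by all phantoms.
#' @return data.frame with one row per phantom: `lengthMm`, `depth`,
#'   `pattern`, `truthMm` (pipeline on perfect labels), `measuredMm`
#'   (pipeline on segmented frames), `analyticMm` (closed-form span).
#' @export
strictureRecoveryExperiment <- function(nPhantoms = 20L,
                                        lengthsMm = seq(4, 30, length.out = nPhantoms),
                                        depths = rep(c(0.5, 0.6, 0.7, 0.8, 0.9),
                                                     length.out = nPhantoms),
                                        seed = 0L,
                                        speckleSigma = 0, psfSigmaPx = 0,
                                        backend = "classical",
                                        thresholdPct = 50,
                                        referenceMethod = "p90",
                                        geometry = AcquisitionGeometry(35, 14, 10, c(0.15, 0.15)),
                                        frameShape = c(96L, 96L),
                                        lumenRadiusMm = 1.8,
                                        spongiosumRadiusMm = 4.2) {
  lengthsMm <- rep(lengthsMm, length.out = nPhantoms)
  depths <- rep(depths, length.out = nPhantoms)
  patterns <- rep(c("dotted", "massive"), length.out = nPhantoms)
  rows <- lapply(seq_len(nPhantoms), function(i) {
    spec <- PhantomSpec(
      geometry = geometry, frameShape = frameShape,
      lumenRadiusMm = lumenRadiusMm,
      spongiosumRadiusMm = spongiosumRadiusMm,
      strictureLengthMm = lengthsMm[i], strictureDepth = depths[i],
      fibrosisPattern = patterns[i],
      speckleSigma = speckleSigma, psfSigmaPx = psfSigmaPx,
      seed = seed + i)
    labels <- generateLabels(spec)
    truth <- groundTruthMeasurement(labels, thresholdPct, referenceMethod)
    stack <- simulateFrames(labels, spec)
    seg <- segmentStack(stack, backend)
    meas <- measureStrictureLength(
      strictureRatioCurve(seg, referenceMethod = referenceMethod),
      thresholdPct = thresholdPct)
    data.frame(lengthMm = lengthsMm[i], depth = depths[i],
               pattern = patterns[i],
               truthMm = truth@lengthMm, measuredMm = meas@lengthMm,
               analyticMm = analyticStrictureSpan(spec, thresholdPct))
  })
  do.call(rbind, rows)
}

#' Read / write a PhantomSpec as JSON
#'
#' @param spec a [PhantomSpec-class].
#' @param path JSON file path.
#' @return `path` invisibly (write) or a [PhantomSpec-class] (read).
#' @export
writePhantomSpec <- function(spec, path) {
  g <- spec@geometry
  jsonlite::write_json(list(
    geometry = list(travel_mm = g@travelMm, scan_time_s = g@scanTimeS,
                    frame_rate_hz = g@frameRateHz, pixel_mm = g@pixelMm),
    frame_shape = spec@frameShape,
    lumen_radius_mm = spec@lumenRadiusMm,
    spongiosum_radius_mm = spec@spongiosumRadiusMm,
    stricture_center_mm = spec@strictureCenterMm,
    stricture_length_mm = spec@strictureLengthMm,
    stricture_depth = spec@strictureDepth,
    fibrosis_pattern = spec@fibrosisPattern,
    fibrosis_fraction = spec@fibrosisFraction,
    echogenicity = as.list(spec@echogenicity),
    speckle_sigma = spec@speckleSigma,
    psf_sigma_px = spec@psfSigmaPx,
    seed = spec@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  PhantomSpec(
    geometry = AcquisitionGeometry(j$geometry$travel_mm, j$geometry$scan_time_s,
                                   j$geometry$frame_rate_hz,
                                   as.numeric(j$geometry$pixel_mm)),
    frameShape = as.integer(j$frame_shape),
    lumenRadiusMm = j$lumen_radius_mm,
    spongiosumRadiusMm = j$spongiosum_radius_mm,
    strictureCenterMm = j$stricture_center_mm,
    strictureLengthMm = j$stricture_length_mm,
    strictureDepth = j$stricture_depth,
    fibrosisPattern = j$fibrosis_pattern,
    fibrosisFraction = j$fibrosis_fraction,
    echogenicity = unlist(j$echogenicity),
    speckleSigma = j$speckle_sigma,
    psfSigmaPx = j$psf_sigma_px,
    seed = j$seed
  )
}
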