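test_that("label classes partition the volume", {
  spec <- smallPhantomSpec(seed = 3L)
  lab <- generateLabels(spec)
  u <- sort(unique(as.integer(labels3d(lab))))
  expect_true(all(u %in% 0:3))
  expect_setequal(u, 0:3)  # all four classes present with fibrosis on
  expect_identical(dim(lab), c(96L, 96L, 60L))
  expect_equal(voxelDims(lab), c(0.15, 0.15, 35 / 60), tolerance = 1e-12)
})

test_that("no stricture means constant per-slice lumen area", {
  spec <- smallPhantomSpec(strictureLengthMm = 0)
  areas <- lumenAreaPerSlice(generateLabels(spec))
  expect_true(all(areas > 0))
  expect_lte(diff(range(areas)), prod(spec@geometry@pixelMm) + 1e-12)
})

test_that("full-depth stricture obliterates the lumen at its centre", {
  spec <- smallPhantomSpec(strictureDepth = 1)
  lab <- generateLabels(spec)
  areas <- lumenAreaPerSlice(lab)
  z <- (seq_along(areas) - 1) * voxelDims(lab)[3]
  expect_equal(areas[which.min(abs(z - spec@strictureCenterMm))], 0)
})

test_that("per-slice area is non-increasing from stricture edge to centre", {
  spec <- smallPhantomSpec(strictureLengthMm = 20, strictureDepth = 0.9)
  lab <- generateLabels(spec)
  areas <- lumenAreaPerSlice(lab)
  z <- (seq_along(areas) - 1) * voxelDims(lab)[3]
  half <- z >= spec@strictureCenterMm - 10 & z <= spec@strictureCenterMm
  expect_true(all(diff(areas[half]) <= prod(spec@geometry@pixelMm) + 1e-12))
})

test_that("label and frame synthesis are deterministic given the seed", {
  spec <- smallPhantomSpec(speckleSigma = 0.3, psfSigmaPx = 1, seed = 9L)
  lab1 <- generateLabels(spec); lab2 <- generateLabels(spec)
  expect_identical(labels3d(lab1), labels3d(lab2))
  st1 <- simulateFrames(lab1, spec); st2 <- simulateFrames(lab2, spec)
  expect_identical(frames(st1), frames(st2))
  # a different seed perturbs the speckle
  spec2 <- smallPhantomSpec(speckleSigma = 0.3, psfSigmaPx = 1, seed = 10L)
  expect_false(identical(frames(simulateFrames(generateLabels(spec2), spec2)),
                         frames(st1)))
})

test_that("noiseless frames are exact class-intensity maps", {
  spec <- smallPhantomSpec(speckleSigma = 0, psfSigmaPx = 0)
  lab <- generateLabels(spec)
  st <- simulateFrames(lab, spec)
  ec <- spec@echogenicity
  lut <- c(ec[["background"]], ec[["lumen"]], ec[["spongiosum"]],
           ec[["fibrosis"]])
  expect_equal(frames(st),
               array(lut[labels3d(lab) + 1L], dim = dim(lab)),
               tolerance = 1e-15)
})

test_that("speckled frames preserve the echogenicity ordering in the mean", {
  spec <- smallPhantomSpec(speckleSigma = 0.3, psfSigmaPx = 1, seed = 0L)
  lab <- generateLabels(spec)
  st <- simulateFrames(lab, spec)
  cls <- labels3d(lab); fr <- frames(st)
  mLumen <- mean(fr[cls == 1L]); mSpong <- mean(fr[cls == 2L])
  mFib <- mean(fr[cls == 3L])
  seLumen <- sd(fr[cls == 1L]) / sqrt(sum(cls == 1L))
  seSpong <- sd(fr[cls == 2L]) / sqrt(sum(cls == 2L))
  seFib <- sd(fr[cls == 3L]) / sqrt(sum(cls == 3L))
  expect_gt(mSpong - mLumen, 3 * (seLumen + seSpong))
  expect_gt(mFib - mSpong, 3 * (seSpong + seFib))
})

test_that("fibrosis patterns hit their target fraction inside the zone", {
  for (pat in c("dotted", "massive")) {
    spec <- smallPhantomSpec(fibrosisPattern = pat, seed = 4L)
    lab <- generateLabels(spec)
    z <- (seq_len(dim(lab)[3]) - 1) * voxelDims(lab)[3]
    zone <- abs(z - spec@strictureCenterMm) <= spec@strictureLengthMm / 2
    sub <- labels3d(lab)[, , zone]
    frac <- sum(sub == 3L) / sum(sub %in% c(2L, 3L))
    expect_gt(frac, 0.5 * spec@fibrosisFraction)
    expect_lt(frac, 2.0 * spec@fibrosisFraction)
  }
  # massive pattern is one contiguous blob
  spec <- smallPhantomSpec(fibrosisPattern = "massive", seed = 5L)
  fib <- labels3d(generateLabels(spec)) == 3L
  comp <- EBImage::bwlabel(fib)
  expect_equal(max(comp), 1)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(smallPhantomSpec(strictureLengthMm = 80), "scanned extent")
  expect_error(PhantomSpec(lumenRadiusMm = 5, spongiosumRadiusMm = 4),
               "lumenRadiusMm")
  expect_error(smallPhantomSpec(strictureDepth = 1.2), "0, 1")
})

test_that("ground-truth measurement matches the analytic span", {
  spec <- smallPhantomSpec(strictureLengthMm = 14, strictureDepth = 0.8,
                           frames = 140L)
  lab <- generateLabels(spec)
  gt <- groundTruthMeasurement(lab, thresholdPct = 50)
  span <- analyticStrictureSpan(spec, thresholdPct = 50)
  spacing <- voxelDims(lab)[3]
  expect_lte(abs(gt@lengthMm - span), 2 * spacing)
  # shallow stricture never crosses a high threshold
  spec2 <- smallPhantomSpec(strictureDepth = 0.5)
  expect_equal(analyticStrictureSpan(spec2, 90), 0)
  expect_equal(groundTruthMeasurement(generateLabels(spec2), 90)@lengthMm, 0)
  # no-stricture phantom measures zero length
  spec3 <- smallPhantomSpec(strictureLengthMm = 0)
  expect_equal(groundTruthMeasurement(generateLabels(spec3), 50)@lengthMm, 0)
})

test_that("measurement is invariant to in-plane 90-degree rotation", {
  spec <- smallPhantomSpec(seed = 6L)
  lab <- generateLabels(spec)
  rot <- labels3d(lab)
  rot <- aperm(rot, c(2, 1, 3))[dim(rot)[2]:1, , ]  # rotate each slice 90
  labR <- LabelVolume(rot, voxelDims(lab))
  m1 <- groundTruthMeasurement(lab, 50)
  m2 <- groundTruthMeasurement(labR, 50)
  expect_equal(m1@lengthMm, m2@lengthMm)
  expect_equal(m1@referenceAreaMm2, m2@referenceAreaMm2)
})

test_that("phantom specs serialize to JSON and back", {
  td <- withr::local_tempdir()
  spec <- smallPhantomSpec(speckleSigma = 0.25, psfSigmaPx = 1.5, seed = 42L)
  f <- file.path(td, "spec.json")
  writePhantomSpec(spec, f)
  back <- readPhantomSpec(f)
  expect_equal(back@geometry@travelMm, spec@geometry@travelMm)
  expect_identical(back@frameShape, spec@frameShape)
  expect_equal(back@echogenicity, spec@echogenicity)
  expect_identical(back@seed, spec@seed)
  expect_identical(labels3d(generateLabels(back)),
                   labels3d(generateLabels(spec)))
})
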