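test_that("frame count follows scan time times frame rate", {
  expect_identical(computeFrameCount(21, 20), 420L)
  expect_identical(computeFrameCount(1, 1), 1L)
  expect_identical(computeFrameCount(10, 100), 1000L)
  # round half away from zero on non-integral products
  expect_identical(computeFrameCount(0.25, 10), 3L)
  expect_error(computeFrameCount(-1, 10), "positive")
  expect_error(computeFrameCount(10, 0), "positive")
})

test_that("slice spacing divides travel by frame count", {
  expect_equal(round(computeSliceSpacing(35, 420), 4), 0.0833)
  expect_equal(computeSliceSpacing(10, 100), 0.1)
  expect_equal(computeSliceSpacing(35, 1), 35)
  expect_error(computeSliceSpacing(35, 0), "frameCount")
  expect_error(computeSliceSpacing(0, 10), "positive")
})

test_that("travel is conserved: spacing times frame count equals travel", {
  cases <- list(c(35, 21, 20), c(10, 3, 7), c(1.5, 2.5, 13), c(42, 0.25, 10))
  for (cs in cases) {
    n <- computeFrameCount(cs[2], cs[3])
    expect_equal(computeSliceSpacing(cs[1], n) * n, cs[1], tolerance = 1e-12)
  }
})

test_that("geometry accessors and validity behave", {
  g <- AcquisitionGeometry(35, 21, 20, 0.1)
  expect_identical(frameCount(g), 420L)
  expect_equal(sliceSpacing(g), 35 / 420)
  expect_equal(g@pixelMm, c(0.1, 0.1))
  expect_error(AcquisitionGeometry(-1, 21, 20), "positive")
})

test_that("volume assembly stacks frames unchanged and round-trips", {
  g <- AcquisitionGeometry(3, 3, 1, c(0.2, 0.3))
  set.seed(11)
  fr <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  st <- FrameStack(fr, g)
  vol <- assembleVolume(st)
  expect_identical(dim(vol), c(4L, 4L, 3L))
  for (k in 1:3) expect_identical(voxels(vol)[, , k], fr[[k]])
  expect_equal(voxelDims(vol), c(0.2, 0.3, 1))
  back <- disassembleVolume(vol)
  expect_identical(back, fr)
  # spacing lands in voxelMm[3]
  g2 <- AcquisitionGeometry(35, 42, 10, 0.1)  # 420 frames, 0.0833 mm
  expect_equal(round(assembleVolume(
    FrameStack(array(0.5, c(4, 4, 420)), g2))@voxelMm[3], 4),
    0.0833)
})

test_that("stack construction rejects malformed input", {
  g <- AcquisitionGeometry(3, 3, 1, 0.2)
  expect_error(FrameStack(list(), g), "empty")
  expect_error(FrameStack(list(matrix(0, 4, 4), matrix(0, 3, 4),
                               matrix(0, 4, 4)), g), "shape mismatch")
  expect_error(FrameStack(array(0, c(4, 4, 2)), g), "frames")  # count mismatch
  expect_error(FrameStack(array(2, c(4, 4, 3)), g), "\\[0, 1\\]")
})

test_that("axial plane extraction is exact frame selection", {
  g <- AcquisitionGeometry(5, 5, 1, c(0.2, 0.2))
  set.seed(12)
  fr <- lapply(1:5, function(i) matrix(runif(30), 5, 6))
  vol <- assembleVolume(FrameStack(fr, g))
  for (k in c(1L, 3L, 5L)) {
    pl <- extractPlane(vol, "axial", k)
    expect_identical(pl$image, fr[[k]])
    expect_equal(pl$pixelMm, c(0.2, 0.2))
  }
  expect_error(extractPlane(vol, "axial", 6), "out of bounds")
})

test_that("sagittal and coronal re-slices carry anisotropic pixel sizes", {
  spec <- renderPhantomSpec(fibrosisPattern = "none")
  vol <- assembleVolume(simulateFrames(generateLabels(spec), spec))
  sag <- extractPlane(vol, "sagittal", 20)
  expect_identical(dim(sag$image), c(dim(vol)[1], dim(vol)[3]))
  expect_equal(sag$pixelMm, voxelDims(vol)[c(1, 3)])
  cor <- extractPlane(vol, "coronal", offsetMm = 3.9)
  expect_identical(cor$index, 20L)
  # mirror symmetry of the tube phantom about the vertical mid-plane:
  # sagittal planes at mirrored columns are identical
  d <- dim(vol)
  left <- extractPlane(vol, "sagittal", 20)$image
  right <- extractPlane(vol, "sagittal", d[2] + 1L - 20L)$image
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("sagittal slice of a labelled phantom shows the lumen narrowing", {
  spec <- smallPhantomSpec(strictureLengthMm = 14, strictureDepth = 0.9)
  lab <- generateLabels(spec)
  mid <- dim(lab)[2] %/% 2
  sag <- extractPlane(lab, "sagittal", mid)$image
  lumenWidth <- colSums(sag == tissueClasses()[["lumen"]])
  z <- (seq_len(dim(lab)[3]) - 1) * sliceSpacing(spec@geometry)
  centerIdx <- which.min(abs(z - spec@strictureCenterMm))
  outside <- z < spec@strictureCenterMm - 8 | z > spec@strictureCenterMm + 8
  expect_lt(lumenWidth[centerIdx], min(lumenWidth[outside]))
})

test_that("NIfTI volume IO round-trips voxels and voxel sizes", {
  td <- withr::local_tempdir()
  set.seed(13)
  vol <- SonoVolume(array(runif(8 * 8 * 5), c(8, 8, 5)), c(0.11, 0.12, 0.5))
  f <- file.path(td, "v.nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_equal(voxels(back), voxels(vol), tolerance = 1e-12)
  expect_equal(voxelDims(back), voxelDims(vol), tolerance = 1e-6)
  lab <- LabelVolume(array(sample(0:3, 8 * 8 * 5, TRUE), c(8, 8, 5)),
                     c(0.11, 0.12, 0.5))
  fl <- file.path(td, "l.nii.gz")
  writeVolume(lab, fl)
  expect_identical(labels3d(readLabelVolume(fl)), labels3d(lab))
  expect_error(readVolume(file.path(td, "v.foo")), "format")
})

test_that("16-bit TIFF stacks round-trip exactly on the integer grid", {
  td <- withr::local_tempdir()
  g <- AcquisitionGeometry(4, 4, 1, c(0.2, 0.25))
  set.seed(14)
  fr <- array(sample(0:65535, 6 * 6 * 4, TRUE) / 65535, c(6, 6, 4))
  st <- FrameStack(fr, g)
  f <- file.path(td, "s.tif")
  writeStack(st, f)
  back <- readStack(f)
  expect_identical(frames(back), frames(st))
  expect_equal(back@geometry@travelMm, 4)
  expect_equal(back@geometry@pixelMm, c(0.2, 0.25))
})

test_that("PNG-directory stacks round-trip with their geometry sidecar", {
  td <- withr::local_tempdir()
  g <- AcquisitionGeometry(4, 4, 1, 0.2)
  set.seed(15)
  fr <- array(sample(0:255, 5 * 7 * 4, TRUE) / 255, c(5, 7, 4))
  st <- FrameStack(fr, g)
  dd <- file.path(td, "stack")
  writeStack(st, dd)
  back <- readStack(dd)
  expect_identical(frames(back), frames(st))
  # missing sidecar is a metadata error
  file.remove(file.path(dd, "geometry.json"))
  expect_error(readStack(dd), "sidecar")
})
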