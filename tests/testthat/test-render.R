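test_that("transfer-function defaults honour the transparency contract", {
  tf <- TransferFunction()
  expect_equal(tf@opacity[2], 0)                      # lumen transparent
  expect_false(isTRUE(all.equal(tf@colors[4, ], tf@colors[3, ])))
  expect_gt(tf@opacity[4], tf@opacity[3])             # fibrosis stands out
  expect_error(TransferFunction(opacity = c(0, 0, 2, 0)), "0, 1")
})

test_that("lumen transparency zeroes lumen voxels only", {
  spec <- renderPhantomSpec()
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  out <- applyLumenTransparency(vol, lab)
  lum <- labels3d(lab) == 1L
  expect_equal(max(abs(voxels(out)[lum])), 0)
  expect_equal(voxels(out)[!lum], voxels(vol)[!lum], tolerance = 1e-12)
  # volumes without lumen pass through unchanged
  noLum <- LabelVolume(array(0L, dim(vol)), voxelDims(vol))
  expect_equal(voxels(applyLumenTransparency(vol, noLum)), voxels(vol))
  # all-lumen goes all-zero
  allLum <- LabelVolume(array(1L, dim(vol)), voxelDims(vol))
  expect_equal(max(voxels(applyLumenTransparency(vol, allLum))), 0)
  expect_error(applyLumenTransparency(vol,
    LabelVolume(array(0L, c(2, 2, 2)), c(1, 1, 1))), "shape")
})

test_that("all-transparent transfer functions yield the background", {
  spec <- renderPhantomSpec()
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  tf <- TransferFunction(opacity = c(0, 0, 0, 0), background = c(0.1, 0.2, 0.3))
  img <- raycast(vol, lab, tf, Camera(0, 15, c(32L, 32L), 1))
  expect_equal(img[, , 1], matrix(0.1, 32, 32), tolerance = 1e-12)
  expect_equal(img[, , 2], matrix(0.2, 32, 32), tolerance = 1e-12)
  expect_equal(img[, , 3], matrix(0.3, 32, 32), tolerance = 1e-12)
})

test_that("an opaque front voxel occludes the voxel behind it", {
  # two-slice volume viewed along the elevational axis
  lab <- array(0L, c(4, 4, 2))
  lab[, , 1] <- 2L  # class A in front
  lab[, , 2] <- 3L  # class B behind
  vol <- SonoVolume(array(1, c(4, 4, 2)), c(1, 1, 1))
  labv <- LabelVolume(lab, c(1, 1, 1))
  tf <- TransferFunction(opacity = c(0, 0, 1, 1), intensityModulated = FALSE)
  img <- raycast(vol, labv, tf, Camera(0, 90, c(16L, 16L), 1))
  centre <- img[8, 8, ]
  expect_equal(centre, tf@colors[3, ], tolerance = 1e-6)  # front class A
})

test_that("semi-transparent slab compositing matches the closed form", {
  # a slab n voxels deep with per-voxel opacity a, sampled at 1 voxel:
  # accumulated alpha is 1 - (1 - a)^n
  n <- 8L; a <- 0.3
  lab <- array(2L, c(8, 8, n))
  vol <- SonoVolume(array(1, c(8, 8, n)), c(1, 1, 1))
  labv <- LabelVolume(lab, c(1, 1, 1))
  tf <- TransferFunction(opacity = c(0, 0, a, 0), intensityModulated = FALSE,
                         background = c(0, 0, 0))
  img <- raycast(vol, labv, tf, Camera(0, 90, c(8L, 8L), 1))
  expected <- (1 - (1 - a)^n) * tf@colors[3, 1]
  expect_equal(img[4, 4, 1], expected, tolerance = 1e-6)
})

test_that("lumen voxels never contribute under the default transfer function", {
  spec <- renderPhantomSpec()
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  cam <- Camera(30, 25, c(48L, 48L), 0.5)
  withLumen <- raycast(vol, lab, TransferFunction(), cam)
  without <- raycast(applyLumenTransparency(vol, lab), lab,
                     TransferFunction(), cam)
  expect_equal(withLumen, without, tolerance = 1e-12)
})

test_that("rotationally symmetric phantoms render identically at 0 and 90", {
  spec <- renderPhantomSpec(fibrosisPattern = "none")
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  a <- raycast(vol, lab, TransferFunction(), Camera(0, 20, c(48L, 48L), 0.5))
  b <- raycast(vol, lab, TransferFunction(), Camera(90, 20, c(48L, 48L), 0.5))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("fibrosis renders into the green channel near its projection", {
  spec <- renderPhantomSpec(fibrosisPattern = "massive", seed = 5L)
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  cam <- Camera(0, 90, c(40L, 40L), 0.5)  # view along the urethra axis
  img <- raycast(vol, lab, TransferFunction(), cam)
  green <- img[, , 2] - (img[, , 1] + img[, , 3]) / 2
  expect_gt(max(green), 0.05)  # a clearly green region exists
})

test_that("renderViews produces one image per angle and writes files", {
  td <- withr::local_tempdir()
  spec <- renderPhantomSpec()
  lab <- generateLabels(spec)
  vol <- assembleVolume(simulateFrames(lab, spec))
  out <- renderViews(vol, lab, TransferFunction(), angles = c(0, 45, 90, 135),
                     camera = Camera(0, 20, c(24L, 24L), 1), outDir = td)
  expect_identical(length(out), 4L)
  expect_identical(names(out), c("az0", "az45", "az90", "az135"))
  expect_true(all(file.exists(file.path(td,
    c("view_az000.png", "view_az045.png", "view_az090.png",
      "view_az135.png")))))
})

test_that("transfer functions serialize to JSON and back", {
  td <- withr::local_tempdir()
  tf <- TransferFunction(opacity = c(0, 0, 0.1, 0.6),
                         intensityModulated = FALSE,
                         background = c(0.05, 0.05, 0.05))
  f <- file.path(td, "tf.json")
  writeTransferFunction(tf, f)
  back <- readTransferFunction(f)
  expect_equal(back@colors, tf@colors)
  expect_equal(back@opacity, tf@opacity)
  expect_identical(back@intensityModulated, tf@intensityModulated)
  expect_equal(back@background, tf@background)
})
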