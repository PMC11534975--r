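# uro3d

Three-dimensional sonourethrography reconstruction and urethral-stricture
quantification in R.

## What this is for

The surgical repair chosen for a urethral stricture depends on how long
the fibrotic narrowing is. Ultrasound of the water-distended anterior
urethra (sonourethrography) shows the lumen, the corpus spongiosum and
the bright periurethral scar — but a single 2D frame cannot measure a
stricture's extent. When the transducer is swept at constant speed by a
linear stepper motor, the ordered frames become parallel sections of a
calibrated 3D volume: a sweep of 35 mm scanned for 21 s at 20 frames/s
yields 420 frames at 0.0833 mm elevational spacing.

`uro3d` implements the full desk-scale pipeline for users of such sweeps
(urologists, sonographers, imaging researchers):

* **Volume assembly** from PNG/TIFF frame stacks with a JSON geometry
  sidecar, NIfTI volume I/O, multiplanar reformation (axial / sagittal /
  coronal).
* **Four-class segmentation** of each frame — urethral lumen, corpus
  spongiosum, periurethral fibrosis, other tissue — with a deterministic
  classical backend (multi-level Otsu + geodesic reconstruction) and a
  compact trainable encoder–decoder.
* **Stricture quantification.** Per slice at elevational position `z`,

  ```
  stricture ratio (%) = (reference lumen area − slice lumen area)
                        / reference lumen area × 100
  ```

  plotted against `z` this is the *stricture curve*; the *stricture
  length* is the span of the longest contiguous run of slices at or
  above a detection threshold (default 50%, always reported).
* **Segmentation metrics**: per-class DICE and HD95 (pooled directed
  nearest-boundary distances, 95th percentile by linear interpolation),
  pinned by brute-force oracles.
* **Rendering**: emission–absorption raycasting with a fully transparent
  lumen (removes in-lumen reverberation artefacts) and a distinct green
  colormap for fibrosis, from any set of view angles.
* **Method agreement**: Spearman rank correlation and Bland–Altman bias
  / limits of agreement for paired length measurements.
* **A phantom generator** producing ground-truth label volumes and
  speckled B-mode-like stacks of a urethra with a raised-cosine
  stricture of known length/depth, so the whole pipeline is testable
  without patient data.

## A worked example

```r
library(uro3d)

## a 35 mm sweep, 140 frames of 96x96 at 0.15 mm pixels,
## 14 mm stricture of depth 0.8, noiseless
spec <- PhantomSpec(
  geometry = AcquisitionGeometry(35, 14, 10, c(0.15, 0.15)),
  frameShape = c(96L, 96L), lumenRadiusMm = 1.8, spongiosumRadiusMm = 4.2,
  strictureLengthMm = 14, strictureDepth = 0.8,
  speckleSigma = 0, psfSigmaPx = 0, seed = 1L)

labels <- generateLabels(spec)        # ground truth
stack  <- simulateFrames(labels, spec)
seg    <- segmentStack(stack, "classical")

measureStrictureLength(strictureRatioCurve(seg), thresholdPct = 50)
#> StrictureMeasurement: length 8.25 mm (slices 55..87), peak 96.3% at threshold 50%

analyticStrictureSpan(spec, 50)       # closed-form ground-truth span
#> [1] 8.207936

evaluateSegmentation(seg, labels)
#>   class  className      dice   hd95_px hd95_mm defined
#> 1     1      lumen 0.9861874 1.0000000    0.15    TRUE
#> 2     2 spongiosum 0.9998939 0.0000000    0.00    TRUE
#> 3     3   fibrosis 0.9791224 0.0000000    0.00    TRUE
#> 4    NA       mean 0.9884012 0.3333333    0.05    TRUE
```

The measured 8.25 mm is the span over which the ratio stays at or above
50%: a raised-cosine stricture of full width 14 mm and depth 0.8 exceeds
half-calibre loss over only part of its width, and the closed-form value
(8.21 mm) agrees with the pipeline to within a slice spacing.

A thin CLI over the same functions ships in `inst/cli/uro3d.R`
(`assemble`, `simulate`, `segment`, `metrics`, `quantify`, `render`,
`evaluate`).

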