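---
title: "Quantifying anterior urethral strictures from motorized 3D sonourethrography"
author: "uro3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anterior urethral strictures from motorized 3D sonourethrography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uro3d)
```

## The problem

Urethral stricture disease is managed surgically, and the choice of repair
depends critically on the physical length of the fibrotic narrowing.
Sonourethrography (ultrasound of the water-distended urethra) shows the
anterior urethral lumen, the surrounding corpus spongiosum, and the bright
periurethral scar, but a single 2D frame cannot measure a stricture's
extent. When the transducer is translated at constant speed by a linear
stepper motor, the ordered 2D frames become parallel elevational sections
of a 3D volume, and the stricture length becomes measurable from the
per-section lumen calibre.

`uro3d` implements that pipeline at desk scale: volume assembly from frame
stacks, four-class tissue segmentation, stricture-ratio quantification,
segmentation scoring (DICE, HD95), volume rendering with a transparent
lumen, and method-agreement statistics. A parametric phantom generator
provides ground truth, so every stage is testable without patient data.

## Sweep geometry

A constant-speed sweep is fully described by the probe travel $T$ (mm),
scan duration $t$ (s), frame rate $f$ (Hz) and the in-plane pixel size.
The frame count is $N = \mathrm{round}(t \cdot f)$ (round half away from
zero; typical settings give an exact integer — 21 s at 20 Hz yields 420
frames) and the elevational slice spacing is

$$\Delta z = T / N,$$

so 35 mm of travel sampled by 420 frames gives $\Delta z = 0.0833$ mm.
Slice positions use the voxel-centre convention $z_k = k \,\Delta z$,
$k = 0, \dots, N-1$, making the reconstructed extent $N \Delta z = T$.
Axes are stated explicitly because freehand-3D conventions vary: *axial*
is the acquisition plane; *sagittal* fixes an image column (the plane
containing the elevational axis); *coronal* fixes an image row.
Intensities are \[0, 1\] floating point internally; integer formats are
min–max mapped at the I/O boundary (16-bit TIFF stacks round-trip exactly
on the integer grid).

## The stricture curve

For a 4-class label volume (codes: 0 background, 1 lumen, 2 corpus
spongiosum, 3 fibrosis), the per-slice lumen area is the lumen pixel
count times the pixel area. With a reference ("healthy") lumen area
$A_\mathrm{ref}$, each slice's **stricture ratio** is

$$ \mathrm{ratio}(z_k) \;=\; \frac{A_\mathrm{ref} - A(z_k)}{A_\mathrm{ref}} \times 100, $$

clipped below at 0 when a slice exceeds the reference. Plotting the ratio
against $z$ gives the stricture curve; the **stricture length** is the
physical span of the longest contiguous run of slices at or above a
detection threshold (run slice count $\times \Delta z$). Secondary
supra-threshold runs are reported too, so multifocal disease is never
silently collapsed.

Two choices here are genuinely open, and both are explicit configuration:

* **Reference area.** Default: the 90th percentile of the per-slice
  areas. It needs no hand-picked "healthy segment" and is robust while a
  reasonable fraction of the sweep is near baseline calibre. With very
  long strictures relative to the scanned extent the 90th percentile sits
  on the shoulder of the narrowing and mildly underestimates the
  reference; `median`, `max` and `fixed` are selectable alternatives.
* **Detection threshold.** Default 50% — the conventional half-calibre
  stenosis landmark. The threshold is carried inside every measurement
  object, so results are never reported without the cutoff that produced
  them. Measured length is monotonically non-increasing in the threshold.

## The phantom generator

`PhantomSpec()` describes a synthetic urethra: a dark fluid-filled lumen
tube of baseline radius $r_0$ inside a mid-gray corpus spongiosum sleeve,
with a stricture modelled as a raised-cosine reduction of the lumen
radius,

$$ r(z) = r_0\,\bigl(1 - d\, w(z)\bigr), \qquad
   w(z) = \tfrac12\Bigl(1 + \cos\frac{2\pi (z - c)}{L}\Bigr)
   \text{ for } |z - c| \le L/2, $$

where $d \in (0, 1]$ is the depth, $c$ the centre and $L$ the full
width. The raised cosine (rather than a hard notch) makes
ratio-threshold crossings sub-slice and analytically invertible: the span
where the ground-truth ratio exceeds a threshold $\tau$ is
$\frac{L}{\pi} \arccos(2 w_\tau - 1)$ with
$w_\tau = (1 - \sqrt{1 - \tau/100})/d$, which is the closed-form oracle
the recovery tests compare against (agreement is required to within two
slice spacings).

Fibrosis is carved inside the spongiosum within the stricture zone until
a target fraction of zone spongiosum voxels is reached: `"dotted"` places
Poisson-disc-separated spheres of 2–4 voxel radius, `"massive"` grows a
single ellipsoid sized by bisection. B-mode appearance is simulated as
class mean echogenicity, blurred by a Gaussian point-spread function
(`psfSigmaPx`, default 1 px) and multiplied by i.i.d. unit-mean Gamma
speckle with shape $1/\sigma_s^2$ (default $\sigma_s = 0.3$) — the
standard single-parameter fully-developed-speckle approximation. All
synthesis is deterministic given the spec's seed.

Default acquisition parameters are the motorized-sweep conditions (35 mm
travel, 21 s at 20 Hz); test problem sizes are stated below. Echogenicity
defaults (lumen 0.05, background 0.2, spongiosum 0.55, fibrosis 0.95)
are a synthetic convention chosen for class separability — fibrosis
echogenicity is not quantitatively characterized in vivo. What the
phantom deliberately omits: attenuation, refraction, acoustic shadowing
and reverberation artefacts (the rendering stage removes in-lumen
reverberation by transparency rather than modelling it). Passing tests
on phantoms therefore demonstrate the correctness of the measurement
machinery, not segmentation performance on clinical images.

## Segmentation backends

The clinical pipeline runs a trained network per frame; this package
ships two backends behind one contract (`segmentStack()`: preprocess each
frame to the working resolution, segment, nearest-neighbour resize of the
label map back to native shape — labels stay integral).

**Classical (default, deterministic).** Frames are banded dark/mid/bright
by exhaustive two-threshold Otsu on a 256-bin histogram. The most central
dark connected component is the lumen, subject to plausibility guards
(at least 9 px, at most 25% of the frame — a dark component covering the
frame is background, not lumen). The corpus spongiosum is recovered by
geodesic reconstruction, seeded from a 9-px ring around the lumen, of
whichever band reconstructs to the larger region: resize-edge transition
pixels can interpose a thin sliver of the "wrong" band between lumen and
sleeve, so the band identity of the sleeve is decided by reconstruction
size rather than by a fixed dark/mid/bright role assignment. Pixels of a
strictly brighter band inside the filled lumen+sleeve region are
fibrosis; everything else is background. The procedure is pure per frame
(idempotent, no state across frames).

**Trainable encoder–decoder.** A compact two-level U-style network
(3×3 convolutions, 2×2 mean-pool downsampling, nearest-neighbour
upsampling with skip concatenation, 4-channel output) trained with
per-pixel cross-entropy plus soft-DICE loss under Adam, implemented
directly on BLAS matrix products (im2col) so training is deterministic
given a seed and runs in seconds on synthetic frames. Defaults chosen at
build time: 64×64 working resolution, 8 base channels, learning rate
1e-2, batch size 2, 5 epochs. On 60 noisy synthetic frames this reaches
validation lumen DICE ≈ 0.95 in 5 epochs; the rare fibrosis class needs
more epochs than that and is the known slow learner. The 256×256 input
convention of the clinical pipeline is the `preprocessFrame()` default;
the synthetic training runs use 64×64 to keep CPU training at desk
scale.

Dataset preparation follows the round-val/test, remainder-train rule:
validation and test receive `round(0.2 n)` items each and training the
remainder — the only rounding convention consistent with a 442/148/148
split of 738 frames at 6:2:2. An optional group id keeps all frames of
one subject inside a single split (sizes then hold approximately).

## Segmentation metrics

DICE is $2|A \cap B| / (|A| + |B|)$, with two empty masks scoring 1.
HD95 extracts boundary pixels (mask pixels 4/6-adjacent to a non-mask
pixel; array borders count), pools the two directed nearest-neighbour
distance sets (Euclidean, spacing-scaled) and returns the 95th
percentile by linear interpolation between order statistics. Three
conventions are pinned deliberately, because implementations differ:
*pooled* percentile rather than the max of two directed percentiles
(the common medical-imaging choice), *linear-interpolation* percentile,
and *undefined on empty masks* — an empty prediction raises an error
rather than scoring 0, so empty masks are never silently rewarded.
Exactness is enforced by brute-force oracles on small random masks; at
volume scale the same distances are computed by an exact
expanding-shell grid search (integer offsets scanned in nondecreasing
physical length; the first hit is the nearest neighbour).

## Rendering

Rendering follows the clinical visual contract: lumen voxels are set to
0 — equivalently fully transparent — which removes in-lumen reflection
and reverberation artefacts, and fibrosis receives an opacity function
and colormap distinct from all other tissue (default: green, opacity an
order of magnitude above the spongiosum's warm gray). The renderer is an
emission–absorption raycaster: orthographic rays, front-to-back alpha
compositing, trilinear intensity sampling, nearest-neighbour label
sampling, per-sample opacity corrected for step length as
$1-(1-\alpha)^{s}$ with $s$ the step in voxel units. Physically based
light transport is out of scope by design — the visual contract
(transparent lumen, distinct fibrosis, multi-angle views) survives in
the deterministic formulation, and determinism is what makes the
rendering testable: occlusion, transparency-invariance and
rotational-symmetry checks hold to numerical tolerance. Fully
transparent classes are blanked before intensity interpolation so their
voxels cannot bleed into neighbouring samples; with that rule, rendering
a volume with or without lumen intensities zeroed yields bit-identical
images.

## Agreement statistics

Method agreement between measured and reference stricture lengths uses
Spearman rank correlation (Pearson on average ranks, tie-corrected;
undefined for constant vectors, which raise an error) and Bland–Altman
analysis: bias = mean difference, limits of agreement =
bias ± 1.96 × SD with the sample (n−1) SD. The 1.96 multiplier is the
standard normal-approximation choice and is configurable. Incomplete
pairs are dropped with a message; a single remaining pair is an error,
not a degenerate estimate.

## Problem sizes and numerical choices

The test and validation runs use the following sizes, chosen as sensible
desk-scale defaults:

* Recovery experiment: 20 phantoms, stricture lengths 4–30 mm, depths
  0.5–0.9 (dotted and massive fibrosis alternating), noiseless frames,
  96×96 at 0.15 mm pixels, 140 slices over 35 mm (0.25 mm spacing),
  classical backend, threshold 50%, 90th-percentile reference. Expected:
  mean absolute length error ≤ 1 mm against the pipeline run on perfect
  labels (observed: exact agreement), Spearman ≥ 0.95 (observed: 1.0).
* Trainable-backend check: 60 frames (speckle 0.2, PSF 1 px), 6:2:2
  split, 5 epochs, seed fixed.
* Oracle suites: 50 random mask pairs ≤ 16×16 against exhaustive brute
  force at 1e-9.

Other numerical choices: frame counts round half away from zero;
min–max normalization maps constant frames to all-zero; Otsu banding
uses 256 histogram bins; lumen plausibility guards are 9 px minimum and
25% of the frame maximum; ties among equally long supra-threshold runs
go to the first; degenerate inputs (no lumen anywhere, all-zero areas,
empty masks, constant correlation inputs) raise typed errors rather
than returning sentinel values.

## Known limitations

* The classical backend assumes the lumen is the most central dark
  structure and the sleeve surrounds it — true for phantoms and for the
  intended anatomy, untested on clinical B-mode.
* The phantom's straight tube matches a straightened, extended penis;
  no centerline-curvature correction is applied, so lengths are measured
  along the elevational axis.
* The trainable backend is a compact reference implementation for
  synthetic data, not a re-implementation of a clinical-scale
  auto-configuring segmentation framework.
* Rendering is emission–absorption only; no global illumination, no
  interactive viewing, no mesh export.

## A worked example

```{r example, eval = FALSE}
spec <- PhantomSpec(
  geometry = AcquisitionGeometry(35, 14, 10, c(0.15, 0.15)),
  frameShape = c(96L, 96L), lumenRadiusMm = 1.8, spongiosumRadiusMm = 4.2,
  strictureLengthMm = 14, strictureDepth = 0.8,
  speckleSigma = 0, psfSigmaPx = 0, seed = 1L)
labels <- generateLabels(spec)
stack <- simulateFrames(labels, spec)
seg <- segmentStack(stack, "classical")
curve <- strictureRatioCurve(seg)
measureStrictureLength(curve, thresholdPct = 50)
analyticStrictureSpan(spec, 50)
```
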