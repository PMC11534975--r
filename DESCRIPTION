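Package: uro3d
Title: Three-Dimensional Sonourethrography Reconstruction and Stricture
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for anterior urethral stricture assessment
    from freehand 3D ultrasound. Assembles ordered stacks of 2D B-mode
    frames acquired with a linear stepper motor into calibrated volumes,
    segments each frame into four tissue classes (urethral lumen, corpus
    spongiosum, periurethral fibrosis, other tissue), computes per-slice
    lumen areas, the stricture-ratio curve and the physical stricture
    length, evaluates segmentations with DICE and HD95, renders the
    urethra with a transparent lumen and highlighted fibrosis by
    emission-absorption raycasting, and reports method agreement
    (Spearman correlation, Bland-Altman). Includes a parametric phantom
    generator producing ground-truth label volumes and speckled
    B-mode-like frame stacks so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    RNifti,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Segmentation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agreement.R'
    'geometry.R'
    'io.R'
    'metrics.R'
    'phantom.R'
    'quantify.R'
    'render.R'
    'resize.R'
    'segmentation.R'
    'unet.R'
    'uro3d-package.R'
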