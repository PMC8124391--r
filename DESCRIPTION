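Package: conjuflow
Title: Motion-Corrected Velocimetry of Conjunctival Microvessel Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies red-blood-cell flow velocity in video of the bulbar
    conjunctival microvasculature. Implements the full analysis chain: optical
    calibration, contrast-index frame quality filtering, two-step motion
    correction (translation registration followed by vessel-template matching),
    vessel segmentation with a compact attention U-Net trained with a Dice
    loss (plus a multiscale Hessian vesselness fallback), skeleton-based
    vessel morphometry, and spatial-temporal-analysis (kymograph) slope
    velocimetry. A synthetic scene generator renders conjunctiva-like video
    with full ground truth (masks, centerlines, per-frame displacement,
    per-vessel velocity) for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'calibration.R'
    'utils.R'
    'morphology.R'
    'velocimetry.R'
    'template_matching.R'
    'segmentation.R'
    'registration.R'
    'pipeline.R'
    'synthetic.R'
    'unet.R'
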