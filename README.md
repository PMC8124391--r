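# conjuflow

Quantifies red-blood-cell flow velocity in video of the human bulbar
conjunctival microvasculature — the one external tissue where cell motion
can be watched directly. Under green illumination, haemoglobin makes
microvessels appear dark on the bright sclera and moving RBC clusters
appear as darker blobs travelling along them; filming for a few seconds and
reading off how fast those blobs move yields a clinically meaningful
microcirculation measurement. The obstacles are eye motion (saccades,
respiratory drift, motion-blurred frames) and the low contrast of the
vessels themselves. `conjuflow` implements the full analysis chain in R:

1. **Optical calibration** — sensor pitch, magnification and frame rate to
   µm/px, field of view and pixels-per-RBC (`opticalConfig()`,
   `fieldOfView()`, `pixelsPerRBC()`).
2. **Frame quality filtering** — the contrast index (mean Sobel edge
   magnitude) rejects motion-blurred frames below 95 % of the maximum and
   picks the sharpest frame as registration template (`selectFrames()`).
3. **Step-1 motion correction** — integer translation registration by
   zero-normalized cross-correlation, removing saccadic jumps
   (`registerTranslation()`).
4. **Vessel segmentation** — a compact attention U-Net (encoder–decoder
   with attention-gated skips, Dice loss, Adam; implemented natively,
   gradients verified against numerical differentiation) trained on
   64 × 64 patches, applied to a 30-frame average by overlap-tiled
   inference (`buildUNet()`, `trainUNet()`, `predictMask()`); a classical
   multiscale-vesselness fallback needs no training
   (`segmentVesselness()`).
5. **Morphometry** — skeletonization, junction detection (3 neighbours =
   bifurcation, > 3 = crossover), segment separation, pixel-count lengths
   and distance-transform diameters (`vesselGraph()`).
6. **Step-2 motion correction** — the longest/thickest vessel, scored by
   `w1*L + w2*D` on min–max-normalized length and diameter, becomes a
   template matched in every frame by the normalized correlation
   coefficient `R = Σ T·I / sqrt(Σ T² · Σ I²)`, cancelling residual drift
   (`selectTemplateVessel()`, `correctSequence()`).
7. **STA velocimetry** — segments ranked by the observability index
   `α·σ̂t + β·L̂` (temporal variance × length); each selected centerline is
   stacked frame-by-frame into a spatial–temporal (kymograph) image whose
   streak slope, found by a directional-projection variance transform, is
   the cluster speed: `v = slope [rows/col] · µm/px / Δt`
   (`observabilityRank()`, `buildSTA()`, `estimateSlopes()`,
   `measureVelocities()`).

A synthetic scene generator (`sceneConfig()`, `renderScene()`) renders
conjunctiva-like video with complete ground truth — vessel masks,
centerlines, diameters, per-vessel velocities, per-frame displacements,
blurred-frame indices — and backs the package's validation end to end.

## Worked example

Render a synthetic recording with one vessel flowing at 0.25 mm/s under
realistic motion and noise, then run the whole pipeline (vesselness
fallback segmentation, no training needed):

```r
library(conjuflow)

cfg <- sceneConfig(seed = 103 + 250, nVessels = 1,
                   velocityRangeMms = c(0.25, 0.25),
                   diameterRangeUm = c(11, 11), noiseSnr = 10)
scene <- renderScene(cfg)
res <- quantifyBloodFlow(scene@sequence, k = 3)
res$velocities[1, c("diameter_um", "length_mm", "velocity_mm_s", "n_streaks")]
#>   diameter_um length_mm velocity_mm_s n_streaks
#> 1    8.351819  0.162532     0.2360561        24
groundTruth(scene)$velocitiesMmS
#> [1] 0.25
```

The pipeline recovered 0.236 mm/s against a ground truth of 0.25 mm/s
(−5.6 %): the report row gives the measured vessel's diameter (8.4 µm here —
the vessel was drawn at 11 µm, but the mask comes from vesselness
segmentation at half scale and is re-upsampled, which thins it slightly),
its centerline length, the mean speed over the 24 detected streaks, and the
streak count.
Frames rejected by the contrast filter and frames flagged by template
matching are excluded from the kymograph automatically.

A thin command-line interface wraps the same functions
(`inst/cli/conjuflow.R`; subcommands `info`, `simulate`, `register`,
`segment`, `stabilize`, `velocity`), e.g.

```sh
Rscript inst/cli/conjuflow.R simulate --out scene/ --seed 7
Rscript inst/cli/conjuflow.R velocity scene/frames.tif --out report.csv
```

## Package layout

- `R/` — S4 classes (`FrameSequence`, `VesselGraph`, `STAImage`, …),
  one file per pipeline stage.
- `src/` — C++ kernels: correlation scans, Zhang–Suen thinning, im2col/GEMM
  and fused batch-norm primitives for the network.
- `vignettes/conjuflow-methods.Rmd` — the model, its assumptions, every
  tunable parameter with its default and rationale, and known limitations.
- `tests/testthat/` — unit and property tests per stage plus the
  end-to-end acceptance suite.
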