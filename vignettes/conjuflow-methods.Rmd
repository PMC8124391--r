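---
title: "Motion-corrected velocimetry of conjunctival microvessel video: methods and design"
author: "conjuflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected velocimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The bulbar conjunctiva is the one external human tissue where individual red
blood cell (RBC) clusters can be watched moving through microvessels.
Filming it for a few seconds under green light (haemoglobin absorbs
strongly near 530 nm, so vessels appear dark on the bright sclera) yields a
video from which flow velocity can be read off — provided two obstacles are
overcome. First, the eye moves: saccades displace the field by tens of
micrometres between frames, respiration adds a continuous few-micrometre
drift, and fast motion blurs individual frames. Second, the vessels
themselves are low-contrast, unevenly illuminated structures that must be
segmented before any of their geometry can be measured.

`conjuflow` implements the full chain: optical calibration, contrast-based
frame quality filtering, two-step motion correction (global translation
registration, then vessel-template matching), vessel segmentation (a
compact attention U-Net trained with a Dice loss, plus a classical
multiscale-Hessian vesselness fallback), skeleton morphometry, and
spatial–temporal analysis (STA, also called kymograph) velocimetry. A
synthetic scene generator renders conjunctiva-like video with complete
ground truth, so every stage can be validated quantitatively.

## Optical calibration

With sensor pixel pitch $p$ (µm) and total magnification $M$, the tissue is
sampled at $p/M$ µm per pixel. The default configuration (`opticalConfig()`)
is $p = 3.45$ µm, $M = 3.798$, 25 fps: 0.908 µm/px, a 2.0 mm × 1.7 mm field
of view on a binned 2208 × 1848 frame, and $7.5 M / p \approx 8.3$ pixels
across a nominal 7.5 µm red blood cell — comfortably above the 4–5 px/RBC
needed for reliable velocimetry.

## Frame quality and step-1 registration

Each frame is scored with a *contrast index*: the mean over all pixels of
the Sobel gradient magnitude. Motion blur smooths edges, so blurred frames
score low; frames below 95 % of the maximum index are discarded (the
comparison is inclusive, so the sharpest frame always survives; index ties
break toward the earliest frame). The maximum-index frame becomes the
registration template.

Each kept frame is then aligned to the template by the integer translation
maximizing the zero-normalized cross-correlation of the overlap region.
Rotation and scaling are not modelled: over a ~3 s recording at this field
of view, residual eye motion is overwhelmingly translational. Design
choices worth noting:

* **Search strategy.** The nominal search radius (default 64 px, enough for
  two full-size saccades in the same direction) is scanned coarse-to-fine:
  frames are halved by 2 × 2 block means until the radius shrinks to ≤ 8 px
  at the coarsest level, and each finer level refines the doubled estimate
  within ±3 px. On every synthetic case we generate this matches the
  exhaustive scan exactly, at a small fraction of its cost.
* **Border fill.** Pixels vacated by the corrective shift are filled with
  the frame median — neutral for later correlation steps.
* **Tie-breaks.** Equal correlation peaks resolve to the smallest
  displacement magnitude, then row-major order, so results are
  deterministic.

## Segmentation

Frames are preprocessed as the training images were: green channel (for RGB
input), 0.5× resize, then contrast-limited adaptive histogram equalization.
CLAHE's clip limit (2.0) and tile grid (8 × 8) are fixed defaults but
configurable; the implementation replicate-pads the image to a tile
multiple and crops afterwards, since tiled equalization requires divisible
dimensions.

Training data are square crops with side uniform in 64–128 px, resized to
64 × 64 (labels nearest-neighbour, re-binarized), so one vessel appears at
several apparent scales. Optional augmentation applies, each with
probability 0.5: rotation ±30°, shear ±0.2, translation ±8 px (we read the
generic "transformation" in the usual augmentation triple as translation),
and linear motion blur of 3–9 px at random angle — geometry moves patch and
label together, blur touches the patch only. Patches are normalized to
zero mean, unit variance (constant patches become zeros).

The segmenter is a three-stage attention U-Net: per stage two 3 × 3
convolutions (stride 1) each followed by batch normalization and ReLU, 2 × 2
max-pooling between stages, a bottom stage without pooling, and a decoder
that upsamples with 3 × 3 stride-2 transposed convolutions, gates each skip
connection with an additive attention gate (1 × 1 projections of skip and
gating signals, ReLU, 1 × 1 + sigmoid, multiplied onto the skip), and
finishes with a 1 × 1 convolution and two-class softmax. Filter counts
double per stage from `baseFilters` (default 32, i.e. 32/64/128 with 256 at
the bottom; the published figure does not print its counts, so the default
is the standard choice). Convolutions carry no bias — the batch-norm shift
absorbs it exactly.

The network, its backpropagation and the Adam optimizer are implemented in
the package on im2col/GEMM primitives (there is no deep-learning framework
dependency); gradients are verified against numerical differentiation in
the test suite. The loss is $1 - \mathrm{Dice}$ with
$\mathrm{Dice} = 2\sum p q / (\sum p^2 + \sum q^2)$ and an $\varepsilon =
10^{-6}$ smoothing term in numerator and denominator to avoid 0/0 on empty
masks. Reference training protocol (`trainConfig()`): Adam at 5 × 10⁻⁵, 150
epochs, 4:1 train/validation split, learning rate × 0.1 after 15 epochs
without validation improvement, best-on-validation weights returned.

Inference averages the first 30 registered frames (moving cells blur out,
faint vessels accumulate contrast), preprocesses, tiles into 64 × 64 windows
at 50 % overlap, normalizes each tile exactly like a training patch, averages
the vessel probabilities in the overlaps, and thresholds at 0.5. Overlap
blending in probability space was chosen over stitching disjoint tiles to
avoid seam artifacts.

*Scaled-down training runs.* The test suite and the acceptance script train
on 2,000 synthetic patches for 20 epochs. At that budget we use
`baseFilters = 2` and Adam at 10⁻³: a small network converges in tens of
epochs on the synthetic task (dark curvilinear structures on a bright
background), whereas the reference rate of 5 × 10⁻⁵ is tuned for 150-epoch
runs on hundreds of thousands of heterogeneous patches. The defaults of
`unetSpec()`/`trainConfig()` remain the reference protocol. Training
patches come from scenes whose frames are first quality-filtered and
registered, with the ground-truth mask moved into the template frame's
coordinates — the same geometry inference sees.

A training-free alternative, `segmentVesselness()`, implements classical
multiscale Hessian vesselness (scale-normalized eigenvalues, blobness
$\beta = 0.5$, structureness constant at half the per-scale maximum,
restricted to the dark-on-bright polarity) with Otsu thresholding and
small-component removal. The end-to-end pipeline uses it when no trained
weights are supplied.

## Morphometry

The vessel mask is thinned to a one-pixel skeleton (Zhang–Suen), then a
cleanup pass deletes redundant *staircase* pixels — non-endpoint pixels with
2–3 neighbours that are already mutually 8-connected — so the skeleton is
minimally thin and the classical neighbour-count rule is exact: 3
neighbours = bifurcation, more = crossover. Pixels with ≥ 4 neighbours are
never dissolved, as they are candidate crossover centres. (On an ideal
plus-crossing, the centre's four arm pixels also exceed three neighbours in
8-connectivity; junctions therefore come in small clusters, which is
harmless since all junction pixels are removed before segments are
separated.)

Short endpoint branches (< 20 px) running into a junction are pruned first:
they are rasterization artifacts of bumpy mask boundaries and would
otherwise fragment long vessels. After junction removal, 8-connected
components shorter than 20 px are discarded; the survivors are traced into
ordered chains from the endpoint with the smaller (row, col).

Segment length is the raw pixel count along the chain (a √2-weighted
diagonal option exists in `segmentTable()` but is off by default, keeping
the simple counting rule). Diameter: for each centerline pixel the
Euclidean distance transform gives the distance $d$ to the nearest
background pixel; the local width is $2d - 1$ (exact for odd discrete
widths, because $d$ is measured centre-to-centre — taking $d$ itself would
be a radius), and the segment diameter is the median across its pixels,
robust to inflation near junctions.

## Step-2 template matching

A single distinctive vessel serves as the tracking anchor. Each segment is
scored $w_1 \hat L + w_2 \hat D$ with min–max-normalized length and
diameter and equal default weights (the selection rule's weights are not
prescribed anywhere; both properties matter equally for a template that
must be visible in every frame), ties to the lower id. The winner's minimum
bounding box, plus a 5 px context margin, is cropped from the template
frame.

Every frame is then searched with the normalized correlation coefficient
$R = \sum T I / \sqrt{\sum T^2 \sum I^2}$ — deliberately *without* mean
subtraction, matching the plain normalized form; a zero-mean variant is
available behind `zeroMean = TRUE` and is preferable under strong
illumination gradients. The displacement of the best match from the
template's reference position is undone by an integer shift (sub-pixel
parabolic peak interpolation exists behind `subPixel = TRUE`, off by
default since residual motion at this stage is of order one pixel). Frames
whose peak correlation falls below 0.5 are flagged and excluded from
velocimetry.

## Velocimetry

Not every vessel shows measurable flow. Segments are ranked by an
observability index $\alpha \hat\sigma_t + \beta \hat L$: $\sigma_t$ is the
mean temporal variance of centerline pixel intensities (passing clusters
modulate the signal), $L$ the segment length (longer vessels let clusters
be followed longer). Both are min–max normalized before weighting — the
index's inputs have incommensurate units, so we normalize exactly as the
template-selection rule prescribes for its length/diameter pair — with
$\alpha = \beta = 0.5$ and the top 15 segments selected by default.

For each selected segment the STA image stacks the centerline's intensity
profile frame by frame: entry $(i, t)$ is centerline pixel $i$ in usable
frame $t$. A cluster moving at $v$ px/frame traces a streak of slope $v$
rows/column. Columns carry their frames' true acquisition times, so frames
dropped by quality filtering or flagged by template matching skew nothing:
the slope-to-velocity conversion uses the mean true inter-column interval.

Slope extraction (the published analysis annotates streaks manually; the
automated estimator is this package's default, with `manualSlope()` as the
annotation fallback):

1. Detrend: subtract each row's temporal median (removing the static
   vessel profile) and negate, so dark streaks become positive.
2. For each angle on a 0.5° grid (slopes capped at 25 rows/col), project
   the matrix along lines of that slope with linear interpolation and an
   extended intercept range, and score the angle by the count-weighted
   variance of the per-line means divided by the number of lines. The
   weighting makes the expected score equal the noise variance at *every*
   angle (line means from $n$ uncorrelated samples have variance
   $\sigma^2/n$), so pure noise produces a flat profile, while a coherent
   streak concentrates energy into few lines at its own angle.
3. Accept the best angle only if its score exceeds twice the median score
   across angles (the anisotropy gate — pure noise fails it and yields an
   *empty* result: velocity is then reported missing, never zero). Refine
   the angle by golden-section search between its grid neighbours, since a
   0.5° grid is too coarse in slope space for steep streaks.
4. Streaks are the peaks of the projection profile at the best angle that
   stand at least 4 noise standard deviations above the profile median,
   where the noise scale is estimated robustly from the profile's first
   differences (several periodic streaks make the profile itself smooth
   and structured; its raw spread would mask the very peaks it is made
   of). Each peak contributes the common slope, and the velocity is the
   mean over streaks of $|s| \cdot \text{µm/px} / \overline{\Delta t}$,
   reported as a speed (sign discarded).

## The synthetic scene generator

`sceneConfig()`/`renderScene()` emulate the acquisition: dark smooth
vessels (piecewise-cubic curves through jittered waypoints) on a bright
background, rasterized at diameters drawn from 8–16 µm at 0.908 µm/px;
Gaussian-profile dark RBC clusters advancing along each centerline at a
constant speed drawn from 0.05–0.4 mm/s (wrapping at the ends so streaks
persist); a smooth tissue-attached illumination field; global displacement
composed of rare saccades (two per recording, 10–30 px) plus sinusoidal
drift (amplitude 5 px, period 3 s), rounded to integer pixels so
registration can be validated for exact recovery; speckle/sensor noise at a
contrast-to-noise ratio of 10; and two motion-blurred frames per recording.
Blur is applied after noise: it stands for intra-frame motion smearing the
whole imaged scene, granular tissue texture included, which is exactly what
makes blurred frames detectable by the contrast index. Frame geometry
defaults to 256 × 256 px at 70 frames, 25 fps — a region-of-interest crop
of the full sensor field, sized so the validation suite runs in minutes.

What the generator does *not* emulate: photorealistic sclera texture,
cardiac-pulsatile velocity modulation, vessel tortuosity extremes,
non-rigid tissue deformation, and sub-pixel global motion (available as an
option but off by default). Passing tests on these scenes therefore
demonstrates correctness of the algorithms under the stated motion and
noise model, not clinical performance on human recordings.

One generator-specific caveat: in *noise-free* renders the contrast index
is dominated by moving cluster edges rather than (absent) tissue texture,
and the 95 % rule then discards sharp frames that merely have fewer cluster
edges. Realistic noise levels (the default) restore the intended behaviour,
where only genuinely blurred frames fall below threshold.

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds (scene seed, patch seed,
  training seed); identical configurations are byte-identical.
* Flat templates, empty vessel graphs, single-frame sequences (temporal
  variance undefined) and centerline pixels on background raise immediate,
  specific errors.
* Empty-vs-empty masks score Dice 1 via the smoothing term; empty slope
  lists propagate as missing velocities.
* Intensities are processed as doubles in [0, 1]; 8- and 16-bit integer
  input is rescaled on read.
* Problem sizes in the validation suite: 256–320 px scenes, 20–70 frames,
  2,000-patch/20-epoch training runs — chosen as the smallest sizes at
  which every stage operates in its intended regime.

## Known limitations

* Integer-pixel correction only (by default): true sub-pixel drift leaves
  up to half a pixel of residual motion.
* The STA estimator assumes one dominant streak orientation per segment;
  bidirectional or strongly pulsatile flow within one segment would blur
  the projection peak.
* Segment identity is lost across crossovers (the graph is deliberately cut
  at junctions), so velocities are per-segment, not per-vessel-tree.
* The scaled-down network is sized for the synthetic task; real conjunctiva
  video should be trained at the reference protocol with the full patch
  budget.
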