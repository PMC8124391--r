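#' @useDynLib conjuflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats median rnorm runif sd spline var
#' @importFrom utils write.csv
NULL

# ---------------------------------------------------------------------------
# Optical calibration
# ---------------------------------------------------------------------------

#' Optical configuration of the imaging system
#'
#' Holds the camera and lens geometry needed to convert between pixels and
#' physical units: sensor pixel pitch (micrometres), total optical
#' magnification, frame rate, and the nominal red-blood-cell diameter used for
#' sampling-density checks. Frame dimensions are optional and only required
#' for the field-of-view computation.
#'
#' @slot pixelPitchUm sensor pixel size in micrometres (> 0).
#' @slot magnification total optical magnification (> 0, dimensionless).
#' @slot fps acquisition frame rate in frames per second (> 0).
#' @slot rbcDiameterUm nominal red blood cell diameter in micrometres.
#' @slot frameWidthPx,frameHeightPx frame dimensions in pixels (NA if unknown).
#'
#' @seealso [opticalConfig()], [micronsPerPixel()], [fieldOfView()],
#'   [pixelsPerRBC()]
#' @export
setClass("OpticalConfig",
  representation(
    pixelPitchUm = "numeric",
    magnification = "numeric",
    fps = "numeric",
    rbcDiameterUm = "numeric",
    frameWidthPx = "numeric",
    frameHeightPx = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  for (nm in c("pixelPitchUm", "magnification", "fps", "rbcDiameterUm")) {
    v <- slot(object, nm)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single finite positive number", nm))
  }
  for (nm in c("frameWidthPx", "frameHeightPx")) {
    v <- slot(object, nm)
    if (length(v) != 1 || (!is.na(v) && (v <= 0 || v != round(v))))
      msg <- c(msg, sprintf("'%s' must be NA or a positive integer", nm))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Frame sequences
# ---------------------------------------------------------------------------

#' Ordered stack of video frames
#'
#' Frames are stored as a numeric array of dimension height x width x time,
#' intensities in \[0, 1\], row-major image convention (first index = row = y,
#' second = column = x). `times` records each frame's acquisition time in
#' seconds; after quality filtering drops frames, the surviving times remain
#' attached so downstream velocimetry uses true inter-frame intervals.
#'
#' @slot frames numeric array (height, width, n).
#' @slot fps nominal frame rate, frames per second.
#' @slot micronsPerPixel tissue-plane scale, micrometres per pixel.
#' @slot times acquisition time of each frame in seconds.
#'
#' @seealso [frameSequence()], [readSequence()], [writeSequence()]
#' @export
setClass("FrameSequence",
  representation(
    frames = "array",
    fps = "numeric",
    micronsPerPixel = "numeric",
    times = "numeric"
  )
)

setValidity("FrameSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("'frames' must be a 3-D array (height, width, n)")
  if (d[3] < 1) return("at least one frame is required")
  if (any(!is.finite(object@frames)) || min(object@frames) < 0)
    return("frame intensities must be finite and non-negative")
  if (length(object@times) != d[3])
    return("'times' must have one entry per frame")
  if (object@fps <= 0 || object@micronsPerPixel <= 0)
    return("'fps' and 'micronsPerPixel' must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# Registration (step-1 motion correction)
# ---------------------------------------------------------------------------

#' Frame quality report from contrast-index filtering
#'
#' @slot indexPerFrame contrast index (mean Sobel edge magnitude) per frame.
#' @slot threshold acceptance threshold, 0.95 of the maximum index.
#' @slot keptIndices 1-based indices of frames meeting the threshold.
#' @slot templateIndex 1-based index of the sharpest frame (the template).
#' @export
setClass("ContrastReport",
  representation(
    indexPerFrame = "numeric",
    threshold = "numeric",
    keptIndices = "integer",
    templateIndex = "integer"
  )
)

setValidity("ContrastReport", function(object) {
  n <- length(object@indexPerFrame)
  if (!length(object@keptIndices)) return("no frames kept")
  if (any(object@keptIndices < 1 | object@keptIndices > n))
    return("kept indices out of range")
  if (!(object@templateIndex %in% object@keptIndices))
    return("template frame must be among the kept frames")
  tol <- 1e-9 * max(abs(object@indexPerFrame), 1)
  if (abs(object@indexPerFrame[object@templateIndex] -
          max(object@indexPerFrame)) > tol)
    return("template frame must attain the maximum contrast index")
  TRUE
})

#' Result of translation registration
#'
#' @slot displacements integer matrix (kept frames x 2, columns dx, dy):
#'   estimated content displacement of each kept frame relative to the
#'   template frame.
#' @slot registered the motion-corrected [FrameSequence-class] (kept frames only,
#'   shifted back by the estimated displacement).
#' @slot report the [ContrastReport-class] used for frame selection.
#' @export
setClass("RegistrationResult",
  representation(
    displacements = "matrix",
    registered = "FrameSequence",
    report = "ContrastReport"
  )
)

setValidity("RegistrationResult", function(object) {
  if (ncol(object@displacements) != 2) return("displacements must be n x 2")
  if (nrow(object@displacements) != dim(object@registered@frames)[3])
    return("one displacement per registered frame required")
  ti <- match(object@report@templateIndex, object@report@keptIndices)
  if (any(object@displacements[ti, ] != 0))
    return("template frame displacement must be (0, 0)")
  TRUE
})

# ---------------------------------------------------------------------------
# Vessel morphology
# ---------------------------------------------------------------------------

#' Labelled vessel centerline segments
#'
#' Each segment is a one-pixel-wide, 8-connected centerline chain obtained by
#' skeletonizing the vessel mask, removing junction pixels (bifurcations and
#' crossovers) and pruning short fragments. Lengths are pixel counts along the
#' chain; diameters come from the Euclidean distance transform of the mask.
#'
#' @slot segments list of per-segment lists with elements `id`, `pixels`
#'   (ordered n x 2 matrix of row, col coordinates), `lengthPx`, `diameterPx`
#'   (NA until [measureDiameters()] is applied).
#' @slot bifurcations,crossovers m x 2 matrices of junction coordinates
#'   (row, col).
#' @slot dim dimensions of the originating mask.
#' @export
setClass("VesselGraph",
  representation(
    segments = "list",
    bifurcations = "matrix",
    crossovers = "matrix",
    dim = "integer"
  )
)

setValidity("VesselGraph", function(object) {
  for (s in object@segments) {
    if (!all(c("id", "pixels", "lengthPx") %in% names(s)))
      return("each segment needs 'id', 'pixels' and 'lengthPx'")
    if (nrow(s$pixels) != s$lengthPx)
      return("segment length must equal its pixel count")
  }
  ids <- vapply(object@segments, `[[`, numeric(1), "id")
  if (anyDuplicated(ids)) return("segment ids must be unique")
  TRUE
})

# ---------------------------------------------------------------------------
# Template matching (step-2 motion correction)
# ---------------------------------------------------------------------------

#' Template vessel selection
#'
#' @slot scores data.frame with per-segment id, normalized length and
#'   diameter, and the weighted selection score.
#' @slot chosenSegmentId id of the winning segment.
#' @slot templateImage cropped patch around the chosen vessel, taken from the
#'   reference frame.
#' @slot box integer (row, col, height, width) of the crop in frame
#'   coordinates (1-based).
#' @export
setClass("TemplateSelection",
  representation(
    scores = "data.frame",
    chosenSegmentId = "numeric",
    templateImage = "matrix",
    box = "integer"
  )
)

#' Result of fine (template-matching) motion correction
#'
#' @slot displacements integer matrix (frames x 2, dx, dy) of residual
#'   displacements found by template matching.
#' @slot corrected the corrected [FrameSequence-class].
#' @slot peakCorrelation per-frame peak normalized correlation coefficient.
#' @slot flagged logical; frames whose peak correlation fell below the
#'   acceptance floor (excluded from downstream velocimetry).
#' @export
setClass("FineCorrection",
  representation(
    displacements = "matrix",
    corrected = "FrameSequence",
    peakCorrelation = "numeric",
    flagged = "logical"
  )
)

setValidity("FineCorrection", function(object) {
  if (any(object@peakCorrelation > 1 + 1e-9) ||
      any(object@peakCorrelation < -1 - 1e-9))
    return("peak correlations must lie in [-1, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Velocimetry
# ---------------------------------------------------------------------------

#' Observability ranking of vessel segments
#'
#' @slot table data.frame with per-segment id, temporal variance `sigmaT`,
#'   `lengthPx`, normalized versions of both and the weighted observability
#'   index, sorted by descending index.
#' @slot selectedIds ids of the top-k segments.
#' @export
setClass("ObservabilityRanking",
  representation(table = "data.frame", selectedIds = "numeric")
)

#' Spatial-temporal analysis (kymograph) image
#'
#' Row i, column t holds the intensity of the i-th centerline pixel in the
#' t-th usable frame; a red-blood-cell cluster moving along the vessel traces
#' a sloped streak whose slope (rows per column) encodes its speed.
#'
#' @slot matrix numeric matrix, rows = centerline position, cols = frames.
#' @slot rowScaleUm micrometres per row (the tissue pixel scale).
#' @slot colTimesS acquisition time (s) of each column's frame.
#' @slot segmentId id of the originating vessel segment.
#' @export
setClass("STAImage",
  representation(
    matrix = "matrix",
    rowScaleUm = "numeric",
    colTimesS = "numeric",
    segmentId = "numeric"
  )
)

setValidity("STAImage", function(object) {
  if (ncol(object@matrix) != length(object@colTimesS))
    return("one column time per STA column required")
  TRUE
})

#' Velocity estimate for one vessel segment
#'
#' @slot slopesPxPerFrame detected streak slopes (rows per column).
#' @slot velocityMmS mean speed in mm/s (NA when no streak was detected).
#' @slot nStreaks number of detected streaks.
#' @slot quality mean streak contrast relative to the background noise level.
#' @slot segmentId id of the measured segment.
#' @export
setClass("VelocityEstimate",
  representation(
    slopesPxPerFrame = "numeric",
    velocityMmS = "numeric",
    nStreaks = "numeric",
    quality = "numeric",
    segmentId = "numeric"
  )
)

# ---------------------------------------------------------------------------
# Segmentation
# ---------------------------------------------------------------------------

#' Patch dataset for segmentation training
#'
#' @slot patches numeric array 64 x 64 x n of normalized image patches.
#' @slot labels numeric array 64 x 64 x n of binary vessel labels.
#' @slot provenance data.frame recording, per patch, the source image id, the
#'   crop box and original crop size, and any augmentations applied.
#' @export
setClass("PatchDataset",
  representation(patches = "array", labels = "array", provenance = "data.frame")
)

setValidity("PatchDataset", function(object) {
  dp <- dim(object@patches)
  dl <- dim(object@labels)
  if (!identical(dp[1:2], c(64L, 64L)) || !identical(dl[1:2], c(64L, 64L)))
    return("patches and labels must be 64 x 64")
  if (dp[3] != dl[3]) return("patch and label counts differ")
  if (!all(object@labels %in% c(0, 1))) return("labels must be binary")
  TRUE
})

#' Attention U-Net model container
#'
#' Wraps the network specification, trainable parameters, batch-normalization
#' running statistics and the training history of the compact attention U-Net
#' used for vessel segmentation.
#'
#' @slot spec list with `stages`, `baseFilters` and derived layer shapes.
#' @slot params named list of weight/bias arrays.
#' @slot state list of batch-norm running means/variances.
#' @slot history data.frame of per-epoch training/validation loss and
#'   learning rate (empty before training).
#' @export
setClass("UNetModel",
  representation(spec = "list", params = "list", state = "list",
                 history = "data.frame")
)

# ---------------------------------------------------------------------------
# Synthetic scenes
# ---------------------------------------------------------------------------

#' Configuration of the synthetic conjunctiva scene generator
#'
#' See [sceneConfig()] for field semantics and defaults.
#' @export
setClass("SceneConfig", representation(params = "list"))

#' Synthetic scene: rendered frames plus full ground truth
#'
#' @slot sequence the rendered [FrameSequence-class].
#' @slot truth list with elements `mask` (binary vessel mask), `centerlines`
#'   (per-vessel ordered coordinates and arc length), `diametersPx`,
#'   `velocitiesMmS`, `velocitiesPxPerFrame`, `displacements` (n x 2 integer
#'   dx, dy per frame), `blurredFrames` (indices).
#' @slot config the [SceneConfig-class] that produced the scene.
#' @export
setClass("SyntheticScene",
  representation(sequence = "FrameSequence", truth = "list",
                 config = "SceneConfig")
)
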