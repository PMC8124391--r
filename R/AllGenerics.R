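#' @include AllClasses.R
NULL

#' Tissue-plane pixel scale
#'
#' Microns imaged per camera pixel, `pixelPitchUm / magnification`.
#'
#' @param x an [OpticalConfig-class] or [FrameSequence-class].
#' @return scalar, micrometres per pixel.
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))

#' @rdname frames
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname frames
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname frames
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Per-frame displacement estimates or ground truth
#'
#' @param x a RegistrationResult, FineCorrection or SyntheticScene.
#' @return integer matrix with columns `dx`, `dy` (pixels, +x right, +y down).
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname segments
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname segments
#' @export
setGeneric("segmentTable", function(x, ...) standardGeneric("segmentTable"))

#' @rdname segments
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @rdname selectFrames
#' @export
setGeneric("keptIndices", function(x) standardGeneric("keptIndices"))

#' @rdname selectFrames
#' @export
setGeneric("templateIndex", function(x) standardGeneric("templateIndex"))

#' Ground truth of a synthetic scene
#'
#' Returns the truth list recorded while rendering: the binary vessel
#' `mask`, per-vessel `centerlines` (dense row/col/arc-length samples),
#' `diametersPx`/`diametersUm`, `velocitiesMmS`/`velocitiesPxPerFrame`, the
#' per-frame applied `displacements`, and `blurredFrames` indices.
#'
#' @param x a [SyntheticScene-class].
#' @return named list (see description).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname buildSTA
#' @export
setGeneric("staMatrix", function(x) standardGeneric("staMatrix"))
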