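#' @include AllClasses.R AllGenerics.R registration.R segmentation.R
#' @include morphology.R template_matching.R velocimetry.R
NULL

#' Quantify blood flow velocity in a microvessel video
#'
#' Runs the full analysis chain on a frame sequence:
#' \enumerate{
#'   \item contrast-index frame filtering and template-frame selection
#'     ([selectFrames()]);
#'   \item step-1 motion correction by translation registration
#'     ([registerTranslation()]);
#'   \item vessel segmentation on a 30-frame average - either a trained
#'     attention U-Net ([predictMask()]) or the training-free multiscale
#'     vesselness fallback ([segmentVesselness()]);
#'   \item skeleton morphometry ([vesselGraph()]);
#'   \item step-2 fine motion correction by vessel-template matching
#'     ([selectTemplateVessel()], [correctSequence()]);
#'   \item observability ranking and spatial-temporal-analysis velocimetry
#'     ([measureVelocities()]).
#' }
#' Segmentation runs at `segScale` resolution (default half, matching the
#' training protocol); the mask is upsampled back to frame resolution for
#' morphometry and velocimetry.
#'
#' @param seq a [FrameSequence-class].
#' @param model optional trained [UNetModel-class]; if `NULL` the vesselness
#'   fallback is used.
#' @param mask optional precomputed binary vessel mask at frame resolution,
#'   skipping the segmentation step.
#' @param keepFraction contrast-index acceptance threshold as a fraction of
#'   the maximum (see [selectFrames()]).
#' @param searchRadius step-1 registration search radius, px.
#' @param segScale segmentation working scale.
#' @param minLen skeleton pruning threshold, px.
#' @param w1,w2 template-vessel selection weights.
#' @param minCorr template-matching acceptance floor.
#' @param alpha,beta,k observability weights and selection count.
#' @param averageN frames averaged for segmentation.
#' @param ... passed to [estimateSlopes()].
#' @return list with elements `report` (ContrastReport), `registration`
#'   (RegistrationResult), `mask`, `graph` (VesselGraph), `selection`
#'   (TemplateSelection), `fine` (FineCorrection), and `velocities` (the
#'   per-segment measurement data.frame from [measureVelocities()]).
#' @export
quantifyBloodFlow <- function(seq, model = NULL, mask = NULL,
                              keepFraction = 0.95,
                              searchRadius = 64, segScale = 0.5,
                              minLen = 20, w1 = 0.5, w2 = 0.5,
                              minCorr = 0.5, alpha = 0.5, beta = 0.5,
                              k = 15, averageN = 30, ...) {
  stopifnot(is(seq, "FrameSequence"))
  report <- selectFrames(seq, keepFraction = keepFraction)
  reg <- registerTranslation(seq, report, searchRadius = searchRadius)
  rseq <- reg@registered
  if (is.null(mask)) {
    if (is.null(model)) {
      avg_n <- min(averageN, nFrames(rseq))
      avg <- apply(rseq@frames[, , seq_len(avg_n), drop = FALSE],
                   c(1, 2), mean)
      small <- segmentVesselness(preprocessFrame(avg, scale = segScale))
    } else {
      small <- predictMask(model, rseq, averageN = averageN,
                           scale = segScale)
    }
    mask <- upscale_mask(small, dim(rseq@frames)[1:2])
    # pixels within the maximum corrective shift of the border carry
    # median fill in some frames, which the averaged image turns into
    # edge artifacts; exclude that band from the vessel mask
    margin <- max(abs(reg@displacements)) + 1
    if (margin > 1) {
      h <- nrow(mask)
      w <- ncol(mask)
      band <- c(seq_len(min(margin, h)), seq(max(1, h - margin + 1), h))
      mask[band, ] <- 0L
      band <- c(seq_len(min(margin, w)), seq(max(1, w - margin + 1), w))
      mask[, band] <- 0L
    }
  }
  graph <- vesselGraph(mask, minLen = minLen)
  tmpl_pos <- match(report@templateIndex, report@keptIndices)
  selection <- selectTemplateVessel(graph, rseq@frames[, , tmpl_pos],
                                    w1 = w1, w2 = w2)
  fine <- correctSequence(rseq, selection, minCorr = minCorr)
  useq <- fine@corrected
  if (any(fine@flagged)) useq <- useq[!fine@flagged]
  vel <- measureVelocities(useq, graph, alpha = alpha, beta = beta, k = k,
                           ...)
  list(report = report, registration = reg, mask = mask, graph = graph,
       selection = selection, fine = fine, velocities = vel)
}

upscale_mask <- function(mask, dims) {
  if (identical(dim(mask), dims)) return(mask)
  up <- from_ebimage(EBImage::resize(as_ebimage(mask * 1), w = dims[2],
                                     h = dims[1], filter = "none"))
  (up > 0.5) * 1L
}
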