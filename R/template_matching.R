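#' @include AllClasses.R AllGenerics.R utils.R morphology.R
NULL

#' Select the template vessel for fine motion correction
#'
#' Scores each vessel segment with a weighted sum of its min-max normalized
#' length and diameter, `w1 * L_hat + w2 * D_hat`, and crops the winning
#' vessel's minimum bounding box (plus a small context margin) out of the
#' reference frame. A long, thick vessel makes a distinctive template that is
#' present in every frame. Ties break toward the lower segment id.
#'
#' @param graph a measured [VesselGraph-class].
#' @param referenceFrame the frame (matrix) to crop the template from,
#'   normally the registration template frame.
#' @param w1,w2 weights for normalized length and diameter (must sum to 1).
#' @param margin context margin around the bounding box, pixels.
#' @return a [TemplateSelection-class].
#' @export
selectTemplateVessel <- function(graph, referenceFrame, w1 = 0.5, w2 = 0.5,
                                 margin = 5) {
  stopifnot(is(graph, "VesselGraph"))
  if (!length(graph@segments)) stopf("vessel graph has no segments")
  if (abs(w1 + w2 - 1) > 1e-9) stopf("w1 + w2 must equal 1")
  tab <- segmentTable(graph)
  if (anyNA(tab$diameter_px))
    stopf("diameters not measured; run measureDiameters() first")
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(1, length(v)) else (v - r[1]) / diff(r)
  }
  Lh <- minmax(tab$length_px)
  Dh <- minmax(tab$diameter_px)
  score <- w1 * Lh + w2 * Dh
  chosen <- tab$id[order(-score, tab$id)][1]
  seg <- graph@segments[[which(tab$id == chosen)]]
  half <- max(1, ceiling(seg$diameterPx / 2))
  r0 <- max(1, min(seg$pixels[, 1]) - half - margin)
  r1 <- min(nrow(referenceFrame), max(seg$pixels[, 1]) + half + margin)
  c0 <- max(1, min(seg$pixels[, 2]) - half - margin)
  c1 <- min(ncol(referenceFrame), max(seg$pixels[, 2]) + half + margin)
  new("TemplateSelection",
      scores = data.frame(id = tab$id, length_px = tab$length_px,
                          diameter_px = tab$diameter_px,
                          length_norm = Lh, diameter_norm = Dh,
                          score = score),
      chosenSegmentId = chosen,
      templateImage = referenceFrame[r0:r1, c0:c1],
      box = as.integer(c(r0, c0, r1 - r0 + 1, c1 - c0 + 1)))
}

setMethod("show", "TemplateSelection", function(object) {
  cat(sprintf("TemplateSelection: segment %d, template %d x %d px at (%d, %d)\n",
              object@chosenSegmentId, object@box[3], object@box[4],
              object@box[1], object@box[2]))
  invisible(NULL)
})

#' Match a template against a frame by normalized correlation
#'
#' Computes the normalized correlation coefficient
#' `R = sum(T * I) / sqrt(sum(T^2) * sum(I^2))` of the template against every
#' valid placement in the frame and reports the displacement of the best
#' placement from the template's reference position. The default form does
#' not subtract local means; `zeroMean = TRUE` switches to the
#' zero-normalized variant, which is more robust under uneven illumination.
#' Ties break toward the smallest displacement magnitude, then row-major
#' order. The score map is invariant to positive scaling of the frame.
#'
#' @param frame image matrix, strictly larger than the template.
#' @param template template matrix.
#' @param refPos integer (row, col) of the template's top-left corner in the
#'   reference frame (1-based); the returned displacement is the matched
#'   position minus `refPos`. Defaults to `c(1, 1)`.
#' @param zeroMean subtract local means before normalizing?
#' @param subPixel refine the peak location by fitting a parabola through
#'   the three scores around the maximum in each axis; `dx`, `dy` then carry
#'   a fractional part. Off by default: the expected residual motion is on
#'   the order of one pixel, and downstream shifting is integer.
#' @return list with `dx`, `dy`, `peak` (peak coefficient) and `scores` (the
#'   full placement score matrix).
#' @export
matchTemplate <- function(frame, template, refPos = c(1L, 1L),
                          zeroMean = FALSE, subPixel = FALSE) {
  if (nrow(template) >= nrow(frame) || ncol(template) >= ncol(frame))
    stopf("template (%d x %d) must be strictly smaller than the frame (%d x %d)",
          nrow(template), ncol(template), nrow(frame), ncol(frame))
  tnorm <- if (zeroMean) stats::sd(template) else sqrt(sum(template^2))
  if (tnorm == 0) stopf("degenerate (flat) template")
  sc <- ncc_match_cpp(frame, template, zeroMean)
  best <- max(sc)
  cand <- which(sc >= best - 1e-12, arr.ind = TRUE)
  dy <- cand[, 1] - refPos[1]
  dx <- cand[, 2] - refPos[2]
  ord <- order(dx^2 + dy^2, cand[, 1], cand[, 2])
  py <- cand[ord[1], 1]
  px <- cand[ord[1], 2]
  ddx <- ddy <- 0
  if (subPixel) {
    para <- function(l, c, r) {
      den <- l - 2 * c + r
      if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (l - r) / den))
    }
    if (py > 1 && py < nrow(sc))
      ddy <- para(sc[py - 1, px], sc[py, px], sc[py + 1, px])
    if (px > 1 && px < ncol(sc))
      ddx <- para(sc[py, px - 1], sc[py, px], sc[py, px + 1])
  }
  dxv <- px - refPos[2] + ddx
  dyv <- py - refPos[1] + ddy
  if (!subPixel) {
    dxv <- as.integer(dxv)
    dyv <- as.integer(dyv)
  }
  list(dx = dxv, dy = dyv, peak = best, scores = sc)
}

#' Step-2 motion correction: template matching
#'
#' Finds the template vessel in every frame of an already-registered
#' sequence, reads off the residual displacement of the match from the
#' template's reference position, and shifts each frame back by it. Frames
#' whose peak correlation falls below `minCorr` are flagged and should be
#' excluded from downstream velocimetry; a warning lists them.
#'
#' @param seq a registered [FrameSequence-class].
#' @param selection a [TemplateSelection-class] whose template was cropped
#'   from this sequence's reference frame.
#' @param minCorr minimum acceptable peak correlation (default 0.5).
#' @param zeroMean passed to [matchTemplate()].
#' @return a [FineCorrection-class].
#' @export
correctSequence <- function(seq, selection, minCorr = 0.5, zeroMean = FALSE) {
  stopifnot(is(seq, "FrameSequence"), is(selection, "TemplateSelection"))
  n <- nFrames(seq)
  ref <- selection@box[1:2]
  disp <- matrix(0L, n, 2, dimnames = list(NULL, c("dx", "dy")))
  peak <- numeric(n)
  out <- array(0, dim(seq@frames))
  for (i in seq_len(n)) {
    f <- seq@frames[, , i]
    m <- matchTemplate(f, selection@templateImage, refPos = ref,
                       zeroMean = zeroMean)
    disp[i, ] <- c(m$dx, m$dy)
    peak[i] <- m$peak
    out[, , i] <- if (m$dx == 0 && m$dy == 0) f else
      shift_frame(f, -m$dx, -m$dy)
  }
  flagged <- peak < minCorr
  if (any(flagged))
    warning(sprintf("%d frame(s) below the correlation floor (%.2f): %s",
                    sum(flagged), minCorr,
                    paste(which(flagged), collapse = ", ")))
  corrected <- new("FrameSequence", frames = out, fps = seq@fps,
                   micronsPerPixel = seq@micronsPerPixel, times = seq@times)
  new("FineCorrection", displacements = disp, corrected = corrected,
      peakCorrelation = peak, flagged = flagged)
}

#' @rdname displacements
#' @export
setMethod("displacements", "FineCorrection", function(x) x@displacements)

setMethod("show", "FineCorrection", function(object) {
  d <- object@displacements
  cat(sprintf("FineCorrection: %d frames, mean |displacement| = (%.2f, %.2f) px, %d flagged\n",
              nrow(d), mean(abs(d[, 1])), mean(abs(d[, 2])),
              sum(object@flagged)))
  invisible(NULL)
})
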