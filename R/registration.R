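#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Contrast index of a frame
#'
#' The contrast index is the mean, over all pixels, of the Sobel edge
#' magnitude sqrt(Gx^2 + Gy^2) computed with the standard 3 x 3 Sobel
#' kernels (replicated borders). Motion-blurred frames score markedly lower
#' than sharp ones, so the index doubles as a blur detector. It is invariant
#' to adding a constant intensity and scales linearly with multiplicative
#' intensity changes.
#'
#' @param frame 2-D numeric matrix, at least 3 x 3.
#' @return scalar contrast index.
#' @export
contrastIndex <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3 || ncol(frame) < 3)
    stopf("'frame' must be a matrix of at least 3 x 3 pixels")
  gx <- conv3x3(frame, sobel_kx)
  gy <- conv3x3(frame, sobel_ky)
  mean(sqrt(gx^2 + gy^2))
}

#' Select sharp frames and the template frame
#'
#' Scores every frame with [contrastIndex()], keeps frames whose index is at
#' least 95% of the maximum (the comparison is inclusive, so the sharpest
#' frame always survives), and designates the frame attaining the maximum as
#' the registration template. Ties are broken toward the earliest frame.
#'
#' @param seq a [FrameSequence-class].
#' @param keepFraction acceptance threshold as a fraction of the maximum
#'   index (default 0.95).
#' @return a [ContrastReport-class].
#' @export
selectFrames <- function(seq, keepFraction = 0.95) {
  stopifnot(is(seq, "FrameSequence"))
  n <- nFrames(seq)
  idx <- vapply(seq_len(n), function(i) contrastIndex(seq@frames[, , i]),
                numeric(1))
  thr <- keepFraction * max(idx)
  kept <- which(idx >= thr)
  new("ContrastReport", indexPerFrame = idx, threshold = thr,
      keptIndices = as.integer(kept),
      templateIndex = as.integer(which.max(idx)))
}

#' @rdname selectFrames
#' @export
setMethod("keptIndices", "ContrastReport", function(x) x@keptIndices)

#' @rdname selectFrames
#' @export
setMethod("templateIndex", "ContrastReport", function(x) x@templateIndex)

setMethod("show", "ContrastReport", function(object) {
  cat(sprintf("ContrastReport: %d/%d frames kept (threshold %.4g), template frame %d\n",
              length(object@keptIndices), length(object@indexPerFrame),
              object@threshold, object@templateIndex))
  invisible(NULL)
})

#' Estimate an integer translation between two frames
#'
#' Maximizes the zero-normalized cross-correlation of the overlap region over
#' integer shifts within `searchRadius`. Ties are broken toward the smallest
#' displacement magnitude, then row-major order.
#'
#' @param ref reference frame (matrix).
#' @param mov moving frame.
#' @param searchRadius maximum shift searched, pixels.
#' @details For large search radii the search is coarse-to-fine: the frames
#'   are repeatedly halved (2 x 2 block means), the full window is scanned at
#'   the coarsest level, and each finer level refines the doubled estimate
#'   within +/-3 px, so the result matches the exhaustive search except in
#'   adversarial cases while staying fast.
#'
#' @return list with `dx`, `dy` (content displacement of `mov` relative to
#'   `ref`) and `score` (peak correlation).
#' @export
estimateShift <- function(ref, mov, searchRadius = 64) {
  if (searchRadius >= min(dim(ref)))
    stopf("search radius (%d) must be smaller than the frame (%d x %d)",
          searchRadius, nrow(ref), ncol(ref))
  pyr_ref <- list(ref)
  pyr_mov <- list(mov)
  nlev <- 0
  while (searchRadius / 2^nlev > 8 && min(dim(pyr_ref[[nlev + 1]])) >= 64) {
    nlev <- nlev + 1
    pyr_ref[[nlev + 1]] <- halve(pyr_ref[[nlev]])
    pyr_mov[[nlev + 1]] <- halve(pyr_mov[[nlev]])
  }
  est <- c(0L, 0L)
  score <- NA_real_
  for (lv in seq(nlev + 1, 1)) {
    r_lv <- if (lv == nlev + 1) ceiling(searchRadius / 2^(lv - 1)) else 3L
    sc <- ncc_shift_cpp(pyr_ref[[lv]], pyr_mov[[lv]], as.integer(r_lv),
                        as.integer(est[1]), as.integer(est[2]))
    pk <- pick_peak(sc, r_lv)
    est <- c(est[1] + pk$dx, est[2] + pk$dy)
    score <- pk$score
    if (lv > 1) est <- est * 2L
  }
  list(dx = as.integer(est[1]), dy = as.integer(est[2]), score = score)
}

halve <- function(m) {
  h <- 2 * (nrow(m) %/% 2)
  w <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(h), seq_len(w)]
  odd_r <- seq(1, h, 2)
  odd_c <- seq(1, w, 2)
  0.25 * (m[odd_r, odd_c] + m[odd_r + 1, odd_c] +
          m[odd_r, odd_c + 1] + m[odd_r + 1, odd_c + 1])
}

pick_peak <- function(sc, radius) {
  best <- max(sc)
  cand <- which(sc >= best - 1e-12, arr.ind = TRUE)
  dy <- cand[, 1] - radius - 1
  dx <- cand[, 2] - radius - 1
  ord <- order(dx^2 + dy^2, cand[, 1], cand[, 2])
  list(dx = as.integer(dx[ord[1]]), dy = as.integer(dy[ord[1]]), score = best)
}

#' Step-1 motion correction: translation registration
#'
#' Registers every kept frame to the template frame by integer-pixel
#' translation: the displacement maximizing the zero-normalized
#' cross-correlation within `searchRadius` is found, the frame is shifted
#' back by it, and vacated borders are filled with the frame's median
#' intensity. This removes the large displacements caused by saccadic eye
#' motion; residual sub-pixel drift is handled afterwards by
#' [correctSequence()].
#'
#' @param seq the original [FrameSequence-class].
#' @param report a [ContrastReport-class] from [selectFrames()] on `seq`.
#' @param searchRadius maximum displacement searched (default 64 px).
#' @return a [RegistrationResult-class] containing the kept, aligned frames.
#' @export
registerTranslation <- function(seq, report = selectFrames(seq),
                                searchRadius = 64) {
  stopifnot(is(seq, "FrameSequence"), is(report, "ContrastReport"))
  kept <- report@keptIndices
  tmpl <- seq@frames[, , report@templateIndex]
  disp <- matrix(0L, length(kept), 2, dimnames = list(NULL, c("dx", "dy")))
  out <- array(0, c(dim(tmpl), length(kept)))
  for (i in seq_along(kept)) {
    f <- seq@frames[, , kept[i]]
    if (kept[i] == report@templateIndex) {
      out[, , i] <- f
      next
    }
    s <- estimateShift(tmpl, f, searchRadius)
    disp[i, ] <- c(s$dx, s$dy)
    out[, , i] <- shift_frame(f, -s$dx, -s$dy)
  }
  registered <- new("FrameSequence", frames = out, fps = seq@fps,
                    micronsPerPixel = seq@micronsPerPixel,
                    times = seq@times[kept])
  new("RegistrationResult", displacements = disp, registered = registered,
      report = report)
}

#' @rdname displacements
#' @export
setMethod("displacements", "RegistrationResult", function(x) x@displacements)

setMethod("show", "RegistrationResult", function(object) {
  d <- object@displacements
  cat(sprintf("RegistrationResult: %d frames, mean |displacement| = (%.2f, %.2f) px\n",
              nrow(d), mean(abs(d[, 1])), mean(abs(d[, 2]))))
  invisible(NULL)
})
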