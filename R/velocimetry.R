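#' @include AllClasses.R AllGenerics.R utils.R morphology.R
NULL

#' Rank vessel segments by flow observability
#'
#' Not every vessel shows a detectable red-blood-cell shift. Vessels with
#' measurable flow have high temporal intensity variance along their
#' centerline (clusters passing change the signal), and longer vessels allow
#' the motion to be followed for longer. The observability index is
#' `alpha * sigmaT_hat + beta * L_hat`, where `sigmaT` is the mean over
#' centerline pixels of the temporal variance of that pixel's intensity, `L`
#' is the segment length, and both are min-max normalized across segments.
#' The `k` highest-index segments are selected.
#'
#' @param seq a motion-corrected [FrameSequence-class] with at least 2 frames.
#' @param graph a [VesselGraph-class].
#' @param alpha,beta weights of normalized temporal variance and length
#'   (must sum to 1).
#' @param k number of segments to select (default 15).
#' @return an [ObservabilityRanking-class].
#' @export
observabilityRank <- function(seq, graph, alpha = 0.5, beta = 0.5, k = 15) {
  stopifnot(is(seq, "FrameSequence"), is(graph, "VesselGraph"))
  if (nFrames(seq) < 2)
    stopf("temporal variance needs at least 2 frames")
  if (abs(alpha + beta - 1) > 1e-9) stopf("alpha + beta must equal 1")
  if (!length(graph@segments)) stopf("vessel graph has no segments")
  n <- nFrames(seq)
  sigma <- vapply(graph@segments, function(s) {
    px <- s$pixels
    traj <- matrix(0, nrow(px), n)
    for (t in seq_len(n)) traj[, t] <- seq@frames[, , t][px]
    mean(apply(traj, 1, stats::var))
  }, numeric(1))
  len <- vapply(graph@segments, `[[`, numeric(1), "lengthPx")
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(1, length(v)) else (v - r[1]) / diff(r)
  }
  idx <- alpha * minmax(sigma) + beta * minmax(len)
  ids <- vapply(graph@segments, `[[`, numeric(1), "id")
  ord <- order(-idx, ids)
  tab <- data.frame(id = ids, sigmaT = sigma, lengthPx = len,
                    sigmaT_norm = minmax(sigma), length_norm = minmax(len),
                    index = idx)[ord, ]
  rownames(tab) <- NULL
  new("ObservabilityRanking", table = tab,
      selectedIds = tab$id[seq_len(min(k, nrow(tab)))])
}

setMethod("show", "ObservabilityRanking", function(object) {
  cat(sprintf("ObservabilityRanking: %d segments ranked, top %d selected\n",
              nrow(object@table), length(object@selectedIds)))
  invisible(NULL)
})

#' Build the spatial-temporal analysis (STA) image of a segment
#'
#' Stacks the vessel centerline's intensity profile frame by frame: entry
#' (i, t) is the intensity of the i-th centerline pixel in the t-th frame.
#' Moving red-blood-cell clusters appear as sloped streaks; the slope in rows
#' per column is the cluster speed in pixels per frame. Column times carry
#' the frames' true acquisition times, so dropped frames do not distort the
#' slope-to-velocity conversion.
#'
#' @param seq a motion-corrected [FrameSequence-class].
#' @param segment one element of `segments(graph)` (a list with `pixels`).
#' @return an [STAImage-class] (rows = centerline position, columns =
#'   frames).
#' @export
buildSTA <- function(seq, segment) {
  stopifnot(is(seq, "FrameSequence"))
  px <- segment$pixels
  d <- dim(seq@frames)
  if (min(px) < 1 || max(px[, 1]) > d[1] || max(px[, 2]) > d[2])
    stopf("centerline pixels fall outside the frame bounds")
  n <- d[3]
  m <- matrix(0, nrow(px), n)
  for (t in seq_len(n)) m[, t] <- seq@frames[, , t][px]
  new("STAImage", matrix = m, rowScaleUm = seq@micronsPerPixel,
      colTimesS = seq@times,
      segmentId = if (!is.null(segment$id)) segment$id else NA_real_)
}

#' @rdname buildSTA
#' @export
setMethod("staMatrix", "STAImage", function(x) x@matrix)

setMethod("show", "STAImage", function(object) {
  cat(sprintf("STAImage: segment %s, %d positions x %d frames (%.3f um/row)\n",
              format(object@segmentId), nrow(object@matrix),
              ncol(object@matrix), object@rowScaleUm))
  invisible(NULL)
})

# Directional projection of a detrended STA matrix: mean intensity along
# lines r = r0 + slope * t (linear interpolation between rows), over an
# extended r0 grid so steep streaks that enter or leave the row range are
# still captured. Returns per-line means and sample counts.
sta_projection <- function(m, slope) {
  nr <- nrow(m)
  nt <- ncol(m)
  tt <- 0:(nt - 1)
  r0 <- seq(floor(min(0, -slope * (nt - 1))) + 1,
            ceiling(max(nr, nr - slope * (nt - 1))))
  acc <- numeric(length(r0))
  cnt <- numeric(length(r0))
  for (j in seq_len(nt)) {
    r <- r0 + slope * tt[j]
    lo <- floor(r)
    w <- r - lo
    ok_lo <- lo >= 1 & lo <= nr
    ok_hi <- (lo + 1) >= 1 & (lo + 1) <= nr
    v <- numeric(length(r0))
    v[ok_lo] <- v[ok_lo] + (1 - w[ok_lo]) * m[lo[ok_lo], j]
    v[ok_hi] <- v[ok_hi] + w[ok_hi] * m[lo[ok_hi] + 1, j]
    acc <- acc + v
    cnt <- cnt + (ok_lo | ok_hi) * 1
  }
  keep <- cnt >= 2
  list(profile = acc[keep] / cnt[keep], count = cnt[keep])
}

# Count-weighted variance of the projection profile, normalized by the number
# of lines. For uncorrelated noise the line means have variance sigma^2/cnt,
# so the cnt-weighting makes the expected score equal sigma^2 at every angle
# (no bias toward steep angles whose lines are short); a coherent streak
# aligned with the projection direction concentrates its energy into a few
# lines and raises the score far above that floor.
projection_score <- function(m, slope) {
  p <- sta_projection(m, slope)
  if (length(p$profile) < 3) return(0)
  mu <- sum(p$count * p$profile) / sum(p$count)
  sum(p$count * (p$profile - mu)^2) / length(p$profile)
}

#' Estimate streak slopes on an STA image
#'
#' The STA matrix is detrended by subtracting each row's temporal median
#' (removing the static vessel profile) and negated so that dark
#' red-blood-cell streaks become positive. The dominant streak orientation is
#' the angle, on a 0.5-degree grid refined by golden-section search,
#' maximizing the variance of the directional projection (summing along
#' lines of that slope); individual streaks are the peaks of the projection
#' profile at the best angle that exceed a robust contrast threshold. An
#' anisotropy gate (best-angle variance must clearly exceed the typical
#' variance across angles) rejects pure-noise images, for which an empty
#' list is returned.
#'
#' @param sta an [STAImage-class] with at least 2 columns.
#' @param maxSlope largest slope searched, rows per column (default 25).
#' @param peakZ robust z-score a projection peak must exceed (default 4).
#' @param anisotropy minimum ratio of best-angle variance to the median
#'   variance across angles (default 2).
#' @return list with `slopes` (rows per column, one per detected streak) and
#'   `quality` (peak z-scores). Empty `slopes` means no streak was found and
#'   the velocity is undefined (not zero).
#' @export
estimateSlopes <- function(sta, maxSlope = 25, peakZ = 4, anisotropy = 2) {
  stopifnot(is(sta, "STAImage"))
  m <- sta@matrix
  if (ncol(m) < 2) stopf("STA image needs at least 2 columns")
  det <- m - apply(m, 1, stats::median)    # remove static vessel profile
  det <- -det                              # dark streaks -> positive
  angles <- seq(-89.5, 89.5, by = 0.5) * pi / 180
  angles <- angles[abs(tan(angles)) <= maxSlope]
  scores <- vapply(tan(angles), function(s) projection_score(det, s),
                   numeric(1))
  best <- which.max(scores)
  if (!is.finite(scores[best]) || scores[best] <= 0)
    return(list(slopes = numeric(0), quality = numeric(0)))
  if (scores[best] < anisotropy * stats::median(scores))
    return(list(slopes = numeric(0), quality = numeric(0)))
  # golden-section refinement of the angle around the coarse peak
  lo <- angles[max(1, best - 1)]
  hi <- angles[min(length(angles), best + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- projection_score(det, tan(c1)); f2 <- projection_score(det, tan(c2))
  for (it in seq_len(40)) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- projection_score(det, tan(c2))
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- projection_score(det, tan(c1))
    }
    if (abs(b - a) < 1e-5) break
  }
  slope <- tan((a + b) / 2)
  # streaks = robust peaks of the projection profile at the best slope.
  # The reference scale is the high-frequency noise of the profile (robust
  # sd of first differences), not the profile's own spread: with several
  # periodic streaks the profile is dominated by smooth streak structure,
  # which must not mask the peaks it is made of.
  p <- sta_projection(det, slope)$profile
  med <- stats::median(p)
  sdev <- stats::mad(diff(p)) / sqrt(2)
  if (sdev == 0) sdev <- stats::mad(p)
  if (sdev == 0) sdev <- stats::sd(p)
  if (!is.finite(sdev) || sdev == 0)
    return(list(slopes = numeric(0), quality = numeric(0)))
  z <- (p - med) / sdev
  is_peak <- z > peakZ &
    z >= c(-Inf, z[-length(z)]) & z >= c(z[-1], -Inf)
  npk <- which(is_peak)
  if (!length(npk)) return(list(slopes = numeric(0), quality = numeric(0)))
  # merge adjacent peak runs
  runs <- split(npk, cumsum(c(1, diff(npk) > 2)))
  slopes <- rep(slope, length(runs))
  quality <- vapply(runs, function(r) max(z[r]), numeric(1))
  list(slopes = unname(slopes), quality = unname(quality))
}

#' Convert streak slopes to a velocity estimate
#'
#' Each slope s (rows per column) corresponds to a speed
#' `|s| * rowScaleUm / dt / 1000` mm/s, where dt is the mean true interval
#' between adjacent STA columns; the segment velocity is the mean over
#' detected streaks. Sign is discarded (speeds are reported).
#'
#' @param slopes numeric vector of slopes (rows per column).
#' @param sta the [STAImage-class] the slopes came from.
#' @param quality optional per-streak contrast scores.
#' @return a [VelocityEstimate-class]; `velocityMmS` is NA when `slopes` is
#'   empty.
#' @export
velocityFromSlopes <- function(slopes, sta, quality = numeric(0)) {
  stopifnot(is(sta, "STAImage"))
  if (!length(slopes)) {
    return(new("VelocityEstimate", slopesPxPerFrame = numeric(0),
               velocityMmS = NA_real_, nStreaks = 0, quality = NA_real_,
               segmentId = sta@segmentId))
  }
  dt <- mean(diff(sta@colTimesS))
  v <- abs(slopes) * sta@rowScaleUm / dt / 1000
  new("VelocityEstimate", slopesPxPerFrame = slopes,
      velocityMmS = mean(v), nStreaks = length(slopes),
      quality = if (length(quality)) mean(quality) else NA_real_,
      segmentId = sta@segmentId)
}

setMethod("show", "VelocityEstimate", function(object) {
  if (object@nStreaks == 0) {
    cat(sprintf("VelocityEstimate: segment %s, no streak detected (velocity undefined)\n",
                format(object@segmentId)))
  } else {
    cat(sprintf("VelocityEstimate: segment %s, %.4f mm/s from %d streak(s)\n",
                format(object@segmentId), object@velocityMmS,
                object@nStreaks))
  }
  invisible(NULL)
})

#' Measure velocities of the most observable segments
#'
#' Runs [observabilityRank()], then [buildSTA()], [estimateSlopes()] and
#' [velocityFromSlopes()] for each selected segment.
#'
#' @param seq motion-corrected [FrameSequence-class].
#' @param graph measured [VesselGraph-class].
#' @param alpha,beta,k see [observabilityRank()].
#' @param ... passed to [estimateSlopes()].
#' @return data.frame with one row per selected segment: id, diameter and
#'   length (pixels and physical units), velocity (mm/s, NA when no streak),
#'   streak count and quality.
#' @export
measureVelocities <- function(seq, graph, alpha = 0.5, beta = 0.5, k = 15,
                              ...) {
  rk <- observabilityRank(seq, graph, alpha = alpha, beta = beta, k = k)
  upp <- seq@micronsPerPixel
  rows <- lapply(rk@selectedIds, function(id) {
    seg <- graph@segments[[which(vapply(graph@segments, `[[`, numeric(1),
                                        "id") == id)]]
    sta <- buildSTA(seq, seg)
    sl <- estimateSlopes(sta, ...)
    est <- velocityFromSlopes(sl$slopes, sta, sl$quality)
    data.frame(id = id,
               diameter_px = seg$diameterPx,
               diameter_um = seg$diameterPx * upp,
               length_px = seg$lengthPx,
               length_mm = seg$lengthPx * upp / 1000,
               velocity_mm_s = est@velocityMmS,
               n_streaks = est@nStreaks,
               quality = est@quality)
  })
  do.call(rbind, rows)
}

#' Manually specified streak slope
#'
#' Annotation fallback to the automated orientation estimator: given two
#' endpoints of a streak on the STA image, returns the implied slope in rows
#' per column, suitable for [velocityFromSlopes()].
#'
#' @param sta an [STAImage-class].
#' @param p1,p2 numeric `c(row, col)` endpoints of the streak.
#' @return slope in rows per column.
#' @export
manualSlope <- function(sta, p1, p2) {
  stopifnot(is(sta, "STAImage"))
  if (p1[2] == p2[2]) stopf("streak endpoints must differ in column")
  (p2[1] - p1[1]) / (p2[2] - p1[2])
}
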