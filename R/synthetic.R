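#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Configure the synthetic conjunctiva scene generator
#'
#' The generator renders dark curvilinear vessels on a bright scleral
#' background (the polarity of green-light conjunctival imaging, where
#' haemoglobin absorbs), with darker red-blood-cell clusters translating
#' along each vessel's centerline at a constant known speed, and emulates the
#' acquisition artifacts the pipeline must undo: rare large inter-frame jumps
#' (saccades), small continuous sinusoidal drift (respiration), occasional
#' motion-blurred frames, smooth uneven illumination, and granular
#' speckle/sensor noise. All randomness derives from `seed`.
#'
#' @param width,height frame size, pixels.
#' @param nFrames number of frames.
#' @param fps frame rate, frames/s.
#' @param micronsPerPixel tissue-plane scale (default 0.908 um/px).
#' @param nVessels number of vessels.
#' @param diameterRangeUm vessel diameter range, micrometres.
#' @param velocityRangeMms red-cell cluster speed range, mm/s.
#' @param clusterLenPx cluster length (Gaussian full width) along the
#'   centerline, pixels.
#' @param clusterSpacingPx spacing between consecutive clusters, pixels.
#' @param clusterContrast intensity deficit of a cluster centre relative to
#'   the open vessel.
#' @param backgroundIntensity scleral background level (0-1).
#' @param vesselIntensity open-vessel (plasma) level (0-1).
#' @param illumAmplitude relative amplitude of the smooth illumination field.
#' @param noiseSnr contrast-to-noise ratio: the vessel/background contrast
#'   divided by the noise standard deviation. `Inf` disables noise.
#' @param saccades either `NULL` (place 2 random saccades with jump size
#'   10-30 px), a list of `list(frame =, dx =, dy =)`, or an empty list for
#'   none.
#' @param driftAmplitudePx,driftPeriodS sinusoidal drift amplitude (px) and
#'   period (s); rendered displacement is rounded to integer pixels so that
#'   registration can recover it exactly.
#' @param blurFrames frame indices receiving motion blur (`NULL`: 2 random
#'   frames; `integer(0)`: none).
#' @param blurLenPx blur kernel length, pixels.
#' @param margin border kept clear of vessels so that saccade-shifted frames
#'   retain every vessel.
#' @param seed RNG seed.
#' @return a [SceneConfig-class].
#' @export
sceneConfig <- function(width = 256, height = 256, nFrames = 70, fps = 25,
                        micronsPerPixel = 0.908, nVessels = 4,
                        diameterRangeUm = c(8, 16),
                        velocityRangeMms = c(0.05, 0.4),
                        clusterLenPx = 24, clusterSpacingPx = 90,
                        clusterContrast = 0.25,
                        backgroundIntensity = 0.85, vesselIntensity = 0.55,
                        illumAmplitude = 0.1, noiseSnr = 10,
                        saccades = NULL, driftAmplitudePx = 5,
                        driftPeriodS = 3, blurFrames = NULL, blurLenPx = 9,
                        margin = 40, seed = 1) {
  p <- as.list(environment())
  stopifnot(width > 2 * p$margin, height > 2 * p$margin, nFrames >= 1,
            fps > 0, micronsPerPixel > 0,
            diff(range(diameterRangeUm)) >= 0, all(diameterRangeUm > 0),
            all(velocityRangeMms >= 0), clusterContrast >= 0,
            backgroundIntensity > vesselIntensity, vesselIntensity > 0,
            noiseSnr > 0)
  new("SceneConfig", params = p)
}

scene_param <- function(cfg, name) cfg@params[[name]]

setMethod("show", "SceneConfig", function(object) {
  p <- object@params
  cat(sprintf("SceneConfig: %d x %d px, %d frames @ %g fps, %d vessels, seed %d\n",
              p$width, p$height, p$nFrames, p$fps, p$nVessels, p$seed))
  invisible(NULL)
})

# Smooth random open curve through jittered waypoints, sampled at ~0.5 px
# steps. Returns dense (row, col) samples and cumulative arc length.
random_curve <- function(width, height, margin, rng_jitter = 18) {
  horizontal <- stats::runif(1) < 0.5
  nw <- 5
  if (horizontal) {
    xs <- seq(margin, width - margin, length.out = nw)
    y0 <- stats::runif(1, margin, height - margin)
    ys <- y0 + cumsum(stats::runif(nw, -rng_jitter, rng_jitter))
    ys <- pmin(pmax(ys, margin), height - margin)
    sx <- stats::spline(xs, ys, n = 40 * nw)
    pts <- cbind(row = sx$y, col = sx$x)
  } else {
    ys <- seq(margin, height - margin, length.out = nw)
    x0 <- stats::runif(1, margin, width - margin)
    xs <- x0 + cumsum(stats::runif(nw, -rng_jitter, rng_jitter))
    xs <- pmin(pmax(xs, margin), width - margin)
    sy <- stats::spline(ys, xs, n = 40 * nw)
    pts <- cbind(row = sy$x, col = sy$y)
  }
  # resample to ~0.5 px arc-length steps
  dd <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(dd))
  s <- seq(0, max(arc), by = 0.5)
  cbind(row = stats::approx(arc, pts[, 1], s)$y,
        col = stats::approx(arc, pts[, 2], s)$y, s = s)
}

#' Generate the vessel layout of a synthetic scene
#'
#' Draws `nVessels` smooth random curves (piecewise cubic through jittered
#' waypoints, non-self-intersecting), assigns each a diameter uniform in the
#' configured range and a cluster speed uniform in the velocity range, and
#' rasterizes the vessels at their diameters. Vessels are laid out
#' independently, so pairs may cross - which is intended, as crossings
#' exercise the junction-detection stage.
#'
#' @param cfg a [SceneConfig-class].
#' @param waypoints optional list of fixed waypoint matrices (row, col), one
#'   per vessel, overriding the random curves.
#' @return list with `mask` (binary matrix), per-vessel `centerlines` (dense
#'   row/col/arc-length samples), `diametersPx`, `diametersUm`,
#'   `velocitiesMmS`, `velocitiesPxPerFrame`, and `arcPixels` (per-vessel
#'   mask-pixel arc-length lookup used by the renderer).
#' @export
generateVessels <- function(cfg, waypoints = NULL) {
  stopifnot(is(cfg, "SceneConfig"))
  p <- cfg@params
  withr::local_seed(p$seed)
  upp <- p$micronsPerPixel
  n <- p$nVessels
  diam_um <- stats::runif(n, p$diameterRangeUm[1], p$diameterRangeUm[2])
  vel <- stats::runif(n, p$velocityRangeMms[1], p$velocityRangeMms[2])
  centerlines <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(waypoints)) {
      wp <- waypoints[[i]]
      dd <- sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)
      arc <- c(0, cumsum(dd))
      s <- seq(0, max(arc), by = 0.5)
      centerlines[[i]] <- cbind(row = stats::approx(arc, wp[, 1], s)$y,
                                col = stats::approx(arc, wp[, 2], s)$y,
                                s = s)
    } else {
      centerlines[[i]] <- random_curve(p$width, p$height, p$margin)
    }
  }
  diam_px <- diam_um / upp
  mask <- matrix(0L, p$height, p$width)
  arc_pixels <- vector("list", n)
  for (i in seq_len(n)) {
    r <- disk_stamp(centerlines[[i]], diam_px[i] / 2, p$height, p$width)
    mask[r$idx] <- 1L
    arc_pixels[[i]] <- r
  }
  list(mask = mask, centerlines = centerlines,
       diametersPx = diam_px, diametersUm = diam_um,
       velocitiesMmS = vel,
       velocitiesPxPerFrame = vel * 1000 / upp / p$fps,
       arcPixels = arc_pixels)
}

# Rasterize a tube of radius `rad` around dense centerline samples; for each
# covered pixel record its arc-length coordinate (from the nearest sample).
disk_stamp <- function(cl, rad, height, width) {
  r_int <- ceiling(rad)
  rows <- pmin(pmax(round(cl[, "row"]), 1), height)
  cols <- pmin(pmax(round(cl[, "col"]), 1), width)
  offs <- expand.grid(dr = -r_int:r_int, dc = -r_int:r_int)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 1e-9, ]
  # vectorized: all (sample, offset) combinations
  nr <- nrow(cl)
  no <- nrow(offs)
  rr <- rep(rows, each = no) + rep(offs$dr, nr)
  cc <- rep(cols, each = no) + rep(offs$dc, nr)
  ss <- rep(cl[, "s"], each = no)
  dist2 <- rep(offs$dr^2 + offs$dc^2, nr)
  ok <- rr >= 1 & rr <= height & cc >= 1 & cc <= width
  rr <- rr[ok]; cc <- cc[ok]; ss <- ss[ok]; dist2 <- dist2[ok]
  lin <- rr + (cc - 1) * height
  # keep, per pixel, the arc length of the closest sample
  ord <- order(lin, dist2)
  lin <- lin[ord]; ss <- ss[ord]
  first <- !duplicated(lin)
  list(idx = lin[first], arc = ss[first])
}

#' Render a synthetic scene
#'
#' Renders the configured number of frames: red-blood-cell clusters advance
#' along each centerline at the vessel's constant speed (wrapping around at
#' the ends so streaks persist for the whole recording), the smooth
#' illumination field multiplies the tissue image, the global displacement
#' (cumulative saccades plus rounded sinusoidal drift) translates the frame,
#' speckle/sensor noise is added, and scheduled frames are motion-blurred
#' (blur is applied last: intra-frame motion smears the whole imaged scene,
#' noise texture included, which is what makes blurred frames detectable by
#' the contrast index). Every quantity needed as ground truth is recorded.
#'
#' @param cfg a [SceneConfig-class].
#' @param vessels optional output of [generateVessels()] (regenerated from
#'   `cfg` if omitted).
#' @return a [SyntheticScene-class].
#' @export
renderScene <- function(cfg, vessels = NULL) {
  stopifnot(is(cfg, "SceneConfig"))
  p <- cfg@params
  if (is.null(vessels)) vessels <- generateVessels(cfg)
  withr::local_seed(p$seed + 1L)
  h <- p$height
  w <- p$width
  n <- p$nFrames
  # static tissue image (no clusters)
  base <- matrix(p$backgroundIntensity, h, w)
  for (i in seq_len(p$nVessels)) base[vessels$arcPixels[[i]]$idx] <-
    p$vesselIntensity
  base <- gaussian_blur(base, 0.7)              # soft vessel edges
  # smooth illumination field (tissue-attached)
  gx <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  gy <- matrix(rep(seq(0, 1, length.out = h), w), h, w)
  phx <- stats::runif(1, 0, 2 * pi)
  phy <- stats::runif(1, 0, 2 * pi)
  illum <- 1 + p$illumAmplitude * (0.6 * sin(2 * pi * 0.7 * gx + phx) +
                                   0.4 * sin(2 * pi * 0.7 * gy + phy))
  # global displacement: cumulative saccades + rounded sinusoidal drift
  sacc <- p$saccades
  if (is.null(sacc)) {
    sfr <- sort(sample(seq(10, n - 5), min(2, max(0, n - 15))))
    sacc <- lapply(sfr, function(f) {
      mag <- stats::runif(1, 10, 30)
      ang <- stats::runif(1, 0, 2 * pi)
      list(frame = f, dx = round(mag * cos(ang)), dy = round(mag * sin(ang)))
    })
  }
  step <- matrix(0, n, 2)
  for (s in sacc) step[s$frame, ] <- step[s$frame, ] + c(s$dx, s$dy)
  tt <- (seq_len(n) - 1) / p$fps
  phase <- stats::runif(1, 0, 2 * pi)
  drift <- cbind(
    round(p$driftAmplitudePx * sin(2 * pi * tt / p$driftPeriodS + phase)),
    round(p$driftAmplitudePx * sin(2 * pi * tt / p$driftPeriodS +
                                   phase + pi / 3)))
  disp <- apply(step, 2, cumsum) + drift
  colnames(disp) <- c("dx", "dy")
  blur_frames <- p$blurFrames
  if (is.null(blur_frames)) blur_frames <- sort(sample(n, min(2, n)))
  noise_sd <- if (is.finite(p$noiseSnr))
    (p$backgroundIntensity - p$vesselIntensity) / p$noiseSnr else 0
  sigma_len <- p$clusterLenPx / 4
  frames_arr <- array(0, c(h, w, n))
  for (t in seq_len(n)) {
    fr <- base
    for (i in seq_len(p$nVessels)) {
      ap <- vessels$arcPixels[[i]]
      L <- max(vessels$centerlines[[i]][, "s"])
      vpx <- vessels$velocitiesPxPerFrame[i]
      if (vpx <= 0 || p$clusterContrast <= 0) next
      starts <- seq(0, L, by = p$clusterSpacingPx)
      pos <- (starts + vpx * (t - 1)) %% L
      dark <- numeric(length(ap$arc))
      for (ctr in pos) {
        d <- abs(ap$arc - ctr)
        d <- pmin(d, L - d)                    # wrapped arc distance
        dark <- dark + exp(-d^2 / (2 * sigma_len^2))
      }
      fr[ap$idx] <- fr[ap$idx] - p$clusterContrast * pmin(dark, 1.6)
    }
    fr <- fr * illum
    if (any(disp[t, ] != 0))
      fr <- shift_frame(fr, disp[t, 1], disp[t, 2],
                        fill = p$backgroundIntensity)
    if (noise_sd > 0) fr <- fr + stats::rnorm(h * w, sd = noise_sd)
    if (t %in% blur_frames)
      fr <- conv_kernel(fr, motion_blur_kernel(p$blurLenPx,
                                               stats::runif(1, 0, pi)))
    frames_arr[, , t] <- clamp01(fr)
  }
  seqc <- new("FrameSequence", frames = frames_arr, fps = p$fps,
              micronsPerPixel = p$micronsPerPixel, times = tt)
  truth <- list(mask = vessels$mask,
                centerlines = vessels$centerlines,
                diametersPx = vessels$diametersPx,
                diametersUm = vessels$diametersUm,
                velocitiesMmS = vessels$velocitiesMmS,
                velocitiesPxPerFrame = vessels$velocitiesPxPerFrame,
                displacements = disp,
                blurredFrames = as.integer(blur_frames))
  new("SyntheticScene", sequence = seqc, truth = truth, config = cfg)
}

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SyntheticScene", function(x) x@truth)

#' @rdname frames
#' @export
setMethod("frames", "SyntheticScene", function(x) frames(x@sequence))

#' @rdname displacements
#' @export
setMethod("displacements", "SyntheticScene", function(x) {
  x@truth$displacements
})

setMethod("show", "SyntheticScene", function(object) {
  p <- object@config@params
  cat(sprintf("SyntheticScene: %d frames %d x %d, %d vessels, velocities %s mm/s\n",
              p$nFrames, p$height, p$width, p$nVessels,
              paste(sprintf("%.3f", object@truth$velocitiesMmS),
                    collapse = "/")))
  invisible(NULL)
})

#' Synthetic training pairs and patch datasets for segmentation
#'
#' `sceneSegmentationPair()` prepares one scene the way the segmenter sees
#' data at inference time: frames are quality-filtered and registered, the
#' first 30 registered frames are averaged and preprocessed at the working
#' scale, and the ground-truth mask is moved into the template frame's
#' coordinates (the registered stack is aligned to the template frame, whose
#' own displacement the mask must follow) and downscaled alongside.
#' `syntheticSegmentationData()` renders `nScenes` independent scenes and
#' extracts random normalized patches from each pair.
#'
#' @param cfg a [SceneConfig-class] (for `sceneSegmentationPair`).
#' @param nScenes number of scenes.
#' @param patchesPerScene patches extracted per scene.
#' @param seed RNG seed (scene rendering and patch sampling).
#' @param scale segmentation working scale (default 0.5).
#' @param width,height scene frame size; the preprocessed image must be at
#'   least 128 px for patch extraction.
#' @param ... further arguments to [sceneConfig()].
#' @return `sceneSegmentationPair()`: list with `image` and `label` at the
#'   working scale; `syntheticSegmentationData()`: a [PatchDataset-class]
#'   combining all scenes.
#' @export
syntheticSegmentationData <- function(nScenes = 4, patchesPerScene = 500,
                                      seed = 1, scale = 0.5, width = 320,
                                      height = 320, ...) {
  sets <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    cfg <- sceneConfig(width = width, height = height,
                       seed = seed + 1000L * i, ...)
    pair <- sceneSegmentationPair(renderScene(cfg), scale = scale)
    sets[[i]] <- extractPatches(pair$image, pair$label, patchesPerScene,
                                seed = seed + i, sourceId = i)
  }
  new("PatchDataset",
      patches = array(unlist(lapply(sets, function(s) s@patches)),
                      c(64, 64, nScenes * patchesPerScene)),
      labels = array(unlist(lapply(sets, function(s) s@labels)),
                     c(64, 64, nScenes * patchesPerScene)),
      provenance = do.call(rbind, lapply(sets, function(s) s@provenance)))
}

#' @rdname syntheticSegmentationData
#' @param scene a rendered [SyntheticScene-class].
#' @export
sceneSegmentationPair <- function(scene, scale = 0.5) {
  stopifnot(is(scene, "SyntheticScene"))
  rep <- selectFrames(scene@sequence)
  reg <- registerTranslation(scene@sequence, rep)
  n <- min(30, nFrames(reg@registered))
  avg <- apply(reg@registered@frames[, , seq_len(n), drop = FALSE],
               c(1, 2), mean)
  img <- preprocessFrame(avg, scale = scale)
  dt <- groundTruth(scene)$displacements[templateIndex(rep), ]
  mask <- shift_frame(groundTruth(scene)$mask, dt[1], dt[2], fill = 0)
  lab <- downscale_mask(mask, dim(img))
  list(image = img, label = lab)
}

downscale_mask <- function(mask, dims) {
  m <- from_ebimage(EBImage::resize(as_ebimage(mask * 1), w = dims[2],
                                    h = dims[1], filter = "none"))
  (m > 0.5) * 1
}
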