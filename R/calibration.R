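#' @include AllClasses.R AllGenerics.R
NULL

#' Create an optical configuration
#'
#' The default values describe a green-light conjunctival imaging setup: a
#' 3.45 um sensor pixel pitch behind a 3.798x magnifying lens train recording
#' at 25 frames per second, which images the tissue at about 0.908 um per
#' pixel and samples a nominal 7.5 um red blood cell with about 8.3 pixels.
#'
#' @param pixelPitchUm camera sensor pixel size, micrometres.
#' @param magnification total optical magnification.
#' @param fps frame rate, frames per second.
#' @param rbcDiameterUm nominal red blood cell diameter, micrometres.
#' @param frameWidthPx,frameHeightPx frame dimensions in pixels (optional,
#'   needed for [fieldOfView()]).
#' @return an [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' micronsPerPixel(cfg)
#' pixelsPerRBC(cfg)
#' @export
opticalConfig <- function(pixelPitchUm = 3.45, magnification = 3.798,
                          fps = 25, rbcDiameterUm = 7.5,
                          frameWidthPx = NA_real_, frameHeightPx = NA_real_) {
  new("OpticalConfig",
      pixelPitchUm = as.numeric(pixelPitchUm),
      magnification = as.numeric(magnification),
      fps = as.numeric(fps),
      rbcDiameterUm = as.numeric(rbcDiameterUm),
      frameWidthPx = as.numeric(frameWidthPx),
      frameHeightPx = as.numeric(frameHeightPx))
}

#' Read an optical configuration from a YAML file
#'
#' Expects a top-level `optics` mapping with fields `pixel_pitch_um`,
#' `magnification`, `fps` and optionally `rbc_diameter_um`,
#' `frame_width_px`, `frame_height_px`.
#'
#' @param path path to the YAML file.
#' @return an [OpticalConfig-class].
#' @export
readOpticsConfig <- function(path) {
  y <- yaml::read_yaml(path)
  o <- if (!is.null(y$optics)) y$optics else y
  opticalConfig(
    pixelPitchUm = o$pixel_pitch_um,
    magnification = o$magnification,
    fps = o$fps,
    rbcDiameterUm = if (!is.null(o$rbc_diameter_um)) o$rbc_diameter_um else 7.5,
    frameWidthPx = if (!is.null(o$frame_width_px)) o$frame_width_px else NA,
    frameHeightPx = if (!is.null(o$frame_height_px)) o$frame_height_px else NA)
}

#' @rdname micronsPerPixel
#' @export
setMethod("micronsPerPixel", "OpticalConfig", function(x) {
  x@pixelPitchUm / x@magnification
})

#' Field of view in millimetres
#'
#' Width and height of the imaged tissue area,
#' `frame dimension (px) * micronsPerPixel / 1000`.
#'
#' @param config an [OpticalConfig-class] with frame dimensions set.
#' @return named numeric vector `c(width_mm, height_mm)`.
#' @examples
#' cfg <- opticalConfig(frameWidthPx = 2208, frameHeightPx = 1848)
#' fieldOfView(cfg)  # about 2.00 mm x 1.68 mm
#' @export
fieldOfView <- function(config) {
  stopifnot(is(config, "OpticalConfig"))
  if (is.na(config@frameWidthPx) || is.na(config@frameHeightPx))
    stopf("frame dimensions must be set to compute the field of view")
  upp <- micronsPerPixel(config)
  c(width_mm = config@frameWidthPx * upp / 1000,
    height_mm = config@frameHeightPx * upp / 1000)
}

#' Pixels imaged per red blood cell
#'
#' `rbcDiameterUm * magnification / pixelPitchUm`. Reliable velocimetry needs
#' at least 4-5 pixels per cell; the default configuration gives about 8.3.
#'
#' @param config an [OpticalConfig-class].
#' @return scalar, pixels per cell diameter.
#' @export
pixelsPerRBC <- function(config) {
  stopifnot(is(config, "OpticalConfig"))
  config@rbcDiameterUm * config@magnification / config@pixelPitchUm
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  pixel pitch   : %.3f um\n", object@pixelPitchUm))
  cat(sprintf("  magnification : %.3fx\n", object@magnification))
  cat(sprintf("  frame rate    : %.2f fps\n", object@fps))
  cat(sprintf("  um per pixel  : %.5f\n", micronsPerPixel(object)))
  cat(sprintf("  px per RBC    : %.2f\n", pixelsPerRBC(object)))
  if (!is.na(object@frameWidthPx) && !is.na(object@frameHeightPx)) {
    fov <- fieldOfView(object)
    cat(sprintf("  field of view : %.3f mm x %.3f mm\n", fov[1], fov[2]))
  }
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# FrameSequence
# ---------------------------------------------------------------------------

#' Construct and access frame sequences
#'
#' `frameSequence()` wraps a height x width x n array (or a list of matrices)
#' into a [FrameSequence-class]; intensities are rescaled to [0, 1] if they
#' arrive as 8- or 16-bit integers. `frames()`, `nFrames()`, `fps()` and
#' `frameTimes()` are the accessors.
#'
#' @param x a 3-D array, a list of equally sized matrices, or (for the
#'   accessors) a `FrameSequence`.
#' @param fps frame rate in frames per second.
#' @param micronsPerPixel tissue-plane scale.
#' @param times optional per-frame acquisition times (s); defaults to
#'   `(0:(n-1)) / fps`.
#' @return `frameSequence()`: a [FrameSequence-class]; `frames()`: the frame
#'   array; `nFrames()`: frame count; `frameTimes()`: times in seconds.
#' @name frames
#' @export
frameSequence <- function(x, fps = 25, micronsPerPixel = 0.908, times = NULL) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (!all(vapply(x, function(f) identical(dim(f), d), logical(1))))
      stopf("all frames must have identical dimensions")
    x <- array(unlist(x, use.names = FALSE), dim = c(d, length(x)))
  }
  if (length(dim(x)) != 3) stopf("'x' must be a 3-D array or list of matrices")
  if (dim(x)[3] < 1) stopf("at least one frame is required")
  mx <- max(x)
  if (mx > 1) {                       # integer DN input: 8- or 16-bit
    scale <- if (mx <= 255) 255 else 65535
    x <- x / scale
  }
  n <- dim(x)[3]
  if (is.null(times)) times <- (seq_len(n) - 1) / fps
  new("FrameSequence", frames = x, fps = as.numeric(fps),
      micronsPerPixel = as.numeric(micronsPerPixel),
      times = as.numeric(times))
}

#' @rdname frames
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname frames
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])

#' @rdname frames
#' @export
setMethod("fps", "FrameSequence", function(x) x@fps)

#' @rdname frames
#' @export
setMethod("frameTimes", "FrameSequence", function(x) x@times)

#' @rdname micronsPerPixel
#' @export
setMethod("micronsPerPixel", "FrameSequence", function(x) x@micronsPerPixel)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, %.2f fps, %.4f um/px\n",
              d[3], d[1], d[2], object@fps, object@micronsPerPixel))
  invisible(NULL)
})

#' Subset frames of a sequence
#'
#' @param x a [FrameSequence-class].
#' @param i frame indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FrameSequence", function(x, i, j, ..., drop = FALSE) {
  new("FrameSequence", frames = x@frames[, , i, drop = FALSE], fps = x@fps,
      micronsPerPixel = x@micronsPerPixel, times = x@times[i])
})

# ---------------------------------------------------------------------------
# Sequence and mask I/O
# ---------------------------------------------------------------------------

read_one_frame <- function(path) {
  low <- tolower(path)
  img <- if (grepl("\\.png$", low)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", low)) {
    tiff::readTIFF(path)
  } else {
    stopf("unsupported frame format: %s", path)
  }
  collapse_rgb(img)
}

# RGB frames are reduced to the green channel (highest haemoglobin contrast,
# lowest background noise); grayscale passes through.
collapse_rgb <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , min(2, dim(img)[3])]
  img
}

#' Read a frame sequence from disk
#'
#' Accepts a multi-page TIFF stack or a directory of numbered PNG/TIFF
#' frames (sorted by file name). RGB input is reduced to the green channel at
#' read time. Intensities are returned in \[0, 1\].
#'
#' @param path TIFF file or frame directory.
#' @param config an [OpticalConfig-class] supplying fps and the pixel scale.
#' @return a [FrameSequence-class].
#' @export
readSequence <- function(path, config = opticalConfig()) {
  if (!file.exists(path)) stopf("path not found: %s", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stopf("no PNG/TIFF frames found in %s", path)
    fr <- lapply(files, read_one_frame)
  } else {
    fr <- tiff::readTIFF(path, all = TRUE)
    fr <- lapply(fr, collapse_rgb)
  }
  d <- dim(fr[[1]])
  if (!all(vapply(fr, function(f) identical(dim(f), d), logical(1))))
    stopf("frames in %s have mixed dimensions", path)
  frameSequence(fr, fps = config@fps,
                micronsPerPixel = micronsPerPixel(config))
}

#' Write a frame sequence to a multi-page TIFF
#'
#' 16-bit output; the write-read round trip is lossless for data quantized to
#' 16 bits.
#'
#' @param seq a [FrameSequence-class].
#' @param path output file path (.tif/.tiff).
#' @return `path`, invisibly.
#' @export
writeSequence <- function(seq, path) {
  stopifnot(is(seq, "FrameSequence"))
  fr <- lapply(seq_len(nFrames(seq)), function(i) clamp01(seq@frames[, , i]))
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read or write a binary mask as PNG (0/255)
#'
#' @param path PNG path.
#' @param mask binary matrix (0/1).
#' @return `readMask()`: a 0/1 integer matrix; `writeMask()`: `path`.
#' @export
readMask <- function(path) {
  m <- collapse_rgb(png::readPNG(path))
  (m > 0.5) * 1L
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}
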