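#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Preprocess a frame for segmentation
#'
#' Three steps: reduce RGB input to the green channel (best haemoglobin
#' contrast), downscale (default 0.5x, e.g. 2208 x 1848 to 1104 x 924), and
#' apply contrast-limited adaptive histogram equalization (CLAHE, clip limit
#' 2.0 on an 8 x 8 tile grid) to lift low-contrast vessels out of the uneven
#' background illumination.
#'
#' @param image 2-D matrix or 3-channel array.
#' @param scale resize factor (default 0.5; 1 disables resizing).
#' @param claheClip CLAHE clip limit.
#' @param claheTiles CLAHE tile grid (tiles per side).
#' @return preprocessed 2-D matrix in \[0, 1\].
#' @export
preprocessFrame <- function(image, scale = 0.5, claheClip = 2,
                            claheTiles = 8) {
  if (!is.numeric(image)) stopf("'image' must be a numeric matrix or array")
  if (length(dim(image)) == 3) image <- image[, , 2]
  if (!is.matrix(image)) stopf("'image' must be 2-D after channel selection")
  img <- as_ebimage(clamp01(image))
  if (scale != 1) {
    img <- EBImage::resize(img, w = round(ncol(image) * scale),
                           h = round(nrow(image) * scale))
  }
  m <- from_ebimage(img)
  if (diff(range(m)) > 0) {
    # CLAHE needs dimensions divisible by the tile grid: replicate-pad,
    # equalize, crop back
    h <- nrow(m)
    w <- ncol(m)
    ph <- claheTiles * ceiling(h / claheTiles)
    pw <- claheTiles * ceiling(w / claheTiles)
    pad <- m[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w))]
    eq <- from_ebimage(EBImage::clahe(as_ebimage(pad), nx = claheTiles,
                                      ny = claheTiles, limit = claheClip))
    m <- eq[seq_len(h), seq_len(w)]
  }
  clamp01(m)
}

normalize_patch <- function(p) {
  s <- stats::sd(p)
  if (s == 0) return(p * 0)
  (p - mean(p)) / s
}

#' Extract random training patches from an image/label pair
#'
#' Draws `n` random square crops with side length uniform in `sizeRange`
#' pixels and resizes each to 64 x 64 (bilinear for the image,
#' nearest-neighbour for the label, which is then re-binarized), so that the
#' same vessel sampled at different crop sizes presents at different apparent
#' scales. Optionally applies random augmentation (see [augmentPatch()]),
#' then normalizes each image patch to zero mean and unit variance (constant
#' patches become all-zero). Fully reproducible given `seed`.
#'
#' @param image preprocessed 2-D image, at least 128 px in each dimension.
#' @param label binary vessel label of the same size.
#' @param n number of patches.
#' @param sizeRange inclusive crop side range, pixels.
#' @param seed RNG seed.
#' @param augment apply random augmentation to each patch?
#' @param sourceId identifier recorded in the provenance table.
#' @return a [PatchDataset-class].
#' @export
extractPatches <- function(image, label, n, sizeRange = c(64, 128),
                           seed = 1, augment = FALSE, sourceId = 1) {
  if (!identical(dim(image), dim(label)))
    stopf("image and label must have the same dimensions")
  if (min(dim(image)) < max(sizeRange))
    stopf("image (%d x %d) is smaller than the largest crop (%d)",
          nrow(image), ncol(image), max(sizeRange))
  stopifnot(n >= 1)
  withr::local_seed(seed)
  patches <- array(0, c(64, 64, n))
  labels <- array(0, c(64, 64, n))
  prov <- data.frame(source = rep(sourceId, n), row0 = 0L, col0 = 0L,
                     size = 0L, augmented = "")
  for (i in seq_len(n)) {
    sizes <- seq(sizeRange[1], sizeRange[2])
    sz <- sizes[sample.int(length(sizes), 1)]
    r0 <- sample.int(nrow(image) - sz + 1, 1)
    c0 <- sample.int(ncol(image) - sz + 1, 1)
    p <- image[r0:(r0 + sz - 1), c0:(c0 + sz - 1)]
    q <- label[r0:(r0 + sz - 1), c0:(c0 + sz - 1)]
    if (sz != 64) {
      p <- from_ebimage(EBImage::resize(as_ebimage(p), w = 64, h = 64))
      q <- from_ebimage(EBImage::resize(as_ebimage(q), w = 64, h = 64,
                                        filter = "none"))
    }
    q <- (q > 0.5) * 1
    aug <- ""
    if (augment) {
      a <- augmentPatch(p, q)
      p <- a$patch
      q <- a$label
      aug <- a$applied
    }
    patches[, , i] <- normalize_patch(p)
    labels[, , i] <- q
    prov$row0[i] <- r0
    prov$col0[i] <- c0
    prov$size[i] <- sz
    prov$augmented[i] <- aug
  }
  new("PatchDataset", patches = patches, labels = labels, provenance = prov)
}

#' Randomly augment a patch/label pair
#'
#' Each operation is applied independently with probability 0.5: rotation
#' (uniform in +/-30 degrees), shear (uniform in +/-0.2), translation
#' (uniform integer in +/-8 px), and linear motion blur (length 3-9 px at a
#' random angle). Geometric operations transform patch and label identically
#' (bilinear vs nearest-neighbour interpolation); blur applies to the patch
#' only. The label is re-binarized afterwards.
#'
#' @param patch 64 x 64 image patch.
#' @param label 64 x 64 binary label.
#' @param rotation `NA` (random coin flip), `FALSE` (off), `TRUE` (forced,
#'   random angle) or an explicit angle in degrees.
#' @param shear as `rotation`, explicit value = shear factor.
#' @param translation as `rotation`, explicit value = integer `c(dx, dy)` px.
#' @param blur as `rotation`, explicit value = blur length in px.
#' @return list with `patch`, `label`, and `applied` (a compact description
#'   of the operations performed).
#' @export
augmentPatch <- function(patch, label, rotation = NA, shear = NA,
                         translation = NA, blur = NA) {
  draw <- function(flag, rand) {
    if (is.logical(flag) && length(flag) == 1 && is.na(flag))
      flag <- stats::runif(1) < 0.5
    if (isTRUE(flag)) return(rand())
    if (isFALSE(flag)) return(NULL)
    flag                                  # explicit value
  }
  theta <- draw(rotation, function() stats::runif(1, -30, 30))
  sh <- draw(shear, function() stats::runif(1, -0.2, 0.2))
  tr <- draw(translation, function() as.integer(round(stats::runif(2, -8, 8))))
  blen <- draw(blur, function() sample(3:9, 1))
  applied <- character(0)
  if (!is.null(theta)) applied <- c(applied, sprintf("rot%.1f", theta))
  if (!is.null(sh)) applied <- c(applied, sprintf("shear%.2f", sh))
  if (!is.null(tr)) applied <- c(applied, sprintf("tr%d,%d", tr[1], tr[2]))
  if (is.null(theta)) theta <- 0
  if (is.null(sh)) sh <- 0
  if (is.null(tr)) tr <- c(0, 0)
  if (theta != 0 || sh != 0 || any(tr != 0)) {
    rad <- theta * pi / 180
    ctr <- (dim(patch) + 1) / 2            # (row, col) centre
    # map in (row, col) space: rotate, then shear rows by columns, then shift
    A <- matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2, 2) %*%
         matrix(c(1, 0, sh, 1), 2, 2)
    off <- ctr - A %*% ctr + c(tr[2], tr[1])   # (dy, dx)
    patch <- affine_rc(patch, A, off, bilinear = TRUE,
                       fill = stats::median(patch))
    label <- affine_rc(label, A, off, bilinear = FALSE, fill = 0)
  }
  if (!is.null(blen)) {
    ang <- stats::runif(1, 0, pi)
    patch <- conv_kernel(patch, motion_blur_kernel(blen, ang))
    applied <- c(applied, sprintf("blur%d", blen))
  }
  list(patch = patch, label = (label > 0.5) * 1,
       applied = paste(applied, collapse = "+"))
}

# Inverse-mapped affine warp in (row, col) convention: for each target pixel
# u, sample the source at A^{-1} (u - off). Bilinear or nearest-neighbour.
affine_rc <- function(m, A, off, bilinear = TRUE, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  tgt <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h))
  src <- t(solve(A) %*% (t(tgt) - as.numeric(off)))
  r <- src[, 1]
  cc <- src[, 2]
  out <- rep(fill, h * w)
  if (bilinear) {
    r0 <- floor(r)
    c0 <- floor(cc)
    fr <- r - r0
    fc <- cc - c0
    ok <- r0 >= 1 & (r0 + 1) <= h & c0 >= 1 & (c0 + 1) <= w
    i <- which(ok)
    v00 <- m[cbind(r0[i], c0[i])]
    v10 <- m[cbind(r0[i] + 1, c0[i])]
    v01 <- m[cbind(r0[i], c0[i] + 1)]
    v11 <- m[cbind(r0[i] + 1, c0[i] + 1)]
    out[i] <- (1 - fr[i]) * ((1 - fc[i]) * v00 + fc[i] * v01) +
      fr[i] * ((1 - fc[i]) * v10 + fc[i] * v11)
    # edge pixels: nearest-neighbour where the 2x2 stencil leaves the image
    edge <- which(!ok & round(r) >= 1 & round(r) <= h &
                    round(cc) >= 1 & round(cc) <= w)
    out[edge] <- m[cbind(round(r[edge]), round(cc[edge]))]
  } else {
    rn <- round(r)
    cn <- round(cc)
    ok <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
    out[ok] <- m[cbind(rn[ok], cn[ok])]
  }
  matrix(out, h, w)
}

#' Dice coefficient
#'
#' `2 * sum(p * q) / (sum(p^2) + sum(q^2))`, with a small smoothing term
#' added to numerator and denominator to avoid 0/0 on empty masks. Used both
#' as the training loss (`1 - Dice`, counteracting the vessel/background
#' class imbalance) and as the evaluation overlap score. Symmetric, bounded
#' in \[0, 1\], and equal to 1 for identical non-empty binary masks.
#'
#' @param pred predicted map, values in \[0, 1\].
#' @param truth binary ground truth of the same shape.
#' @param smooth smoothing constant (default 1e-6).
#' @return scalar in \[0, 1\].
#' @export
diceCoefficient <- function(pred, truth, smooth = 1e-6) {
  if (!identical(dim(pred), dim(truth)) ||
      length(pred) != length(truth))
    stopf("'pred' and 'truth' must have identical shape")
  (2 * sum(pred * truth) + smooth) /
    (sum(pred^2) + sum(truth^2) + smooth)
}

# ---------------------------------------------------------------------------
# Classical vesselness fallback
# ---------------------------------------------------------------------------

#' Multiscale Hessian vesselness
#'
#' Classical curvilinear-structure enhancement: at each Gaussian scale the
#' image Hessian's eigenvalues (|l1| <= |l2|) feed the tubularity response
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2 + l2^2) / (2 c^2)))`,
#' restricted to l2 > 0 for dark vessels on a bright background; the map is
#' the maximum response over scales. Provided as a training-free stand-in
#' for the learned segmenter so the full pipeline can run without weights.
#'
#' @param image 2-D matrix.
#' @param sigmas Gaussian scales in pixels (approximately vessel radius).
#' @param beta blobness sensitivity.
#' @param cFrac structureness constant as a fraction of the maximum
#'   second-derivative norm at each scale.
#' @return vesselness map in \[0, 1\].
#' @export
frangiVesselness <- function(image, sigmas = c(1, 2, 3, 4), beta = 0.5,
                             cFrac = 0.5) {
  best <- matrix(0, nrow(image), ncol(image))
  d2 <- matrix(c(1, -2, 1), 3, 1)
  for (sg in sigmas) {
    sm <- gaussian_blur(image, sg)
    hrr <- conv_kernel(sm, d2)            # d2/drow2
    hcc <- conv_kernel(sm, t(d2))         # d2/dcol2
    hrc <- conv_kernel(sm, matrix(c(0.25, 0, -0.25, 0, 0, 0,
                                    -0.25, 0, 0.25), 3, 3))
    hrr <- hrr * sg^2                      # scale normalization
    hcc <- hcc * sg^2
    hrc <- hrc * sg^2
    tr <- hrr + hcc
    disc <- sqrt(pmax((hrr - hcc)^2 + 4 * hrc^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    swap <- abs(e1) < abs(e2)              # ensure |l1| <= |l2|
    l1 <- ifelse(swap, e1, e2)
    l2 <- ifelse(swap, e2, e1)
    s2 <- l1^2 + l2^2
    cc <- cFrac * sqrt(max(s2))
    if (cc == 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[l2 <= 0] <- 0                        # dark-on-bright polarity
    best <- pmax(best, v)
  }
  best
}

#' Vesselness-based segmentation
#'
#' Thresholds the [frangiVesselness()] map with Otsu's method and removes
#' connected components smaller than `minArea` pixels.
#'
#' @param image 2-D matrix (already preprocessed).
#' @param minArea minimum component area, pixels.
#' @param ... passed to [frangiVesselness()].
#' @return binary mask (0/1 matrix).
#' @export
segmentVesselness <- function(image, minArea = 50, ...) {
  v <- frangiVesselness(image, ...)
  thr <- EBImage::otsu(as_ebimage(v), range = c(0, 1))
  mask <- (v > thr) * 1L
  lab <- label8_cpp(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (max(lab) > 0) {
    area <- tabulate(lab[lab > 0])
    small <- which(area < minArea)
    if (length(small)) mask[lab %in% small] <- 0L
  }
  mask
}
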