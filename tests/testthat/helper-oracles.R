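# Independent oracles and small fixtures used across the suite. These are
# deliberately naive implementations (direct loops over definitions) kept
# separate from the package's optimized code paths.

# Sobel edge magnitude by direct 3x3 convolution with replicated borders.
oracle_sobel_mean <- function(frame) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  h <- nrow(frame)
  w <- ncol(frame)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  px <- function(i, j) frame[min(max(i, 1), h), min(max(j, 1), w)]
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      sx <- 0
      sy <- 0
      for (a in -1:1) {
        for (b in -1:1) {
          sx <- sx + kx[a + 2, b + 2] * px(i + a, j + b)
          sy <- sy + ky[a + 2, b + 2] * px(i + a, j + b)
        }
      }
      gx[i, j] <- sx
      gy[i, j] <- sy
    }
  }
  mean(sqrt(gx^2 + gy^2))
}

# Normalized correlation (no mean subtraction) of a template at every valid
# placement, straight from the definition.
oracle_ncc_map <- function(img, tpl) {
  th <- nrow(tpl)
  tw <- ncol(tpl)
  ho <- nrow(img) - th + 1
  wo <- ncol(img) - tw + 1
  out <- matrix(0, ho, wo)
  t2 <- sum(tpl^2)
  for (y in seq_len(ho)) {
    for (x in seq_len(wo)) {
      patch <- img[y:(y + th - 1), x:(x + tw - 1)]
      out[y, x] <- sum(tpl * patch) / sqrt(t2 * sum(patch^2))
    }
  }
  out
}

# Exhaustive zero-mean shift correlation over a small window.
oracle_best_shift <- function(ref, mov, radius) {
  best <- -Inf
  best_d <- c(0L, 0L)
  h <- nrow(ref)
  w <- ncol(ref)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      ys <- max(1, 1 - dy):min(h, h - dy)
      xs <- max(1, 1 - dx):min(w, w - dx)
      a <- ref[ys, xs]
      b <- mov[ys + dy, xs + dx]
      sc <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
      if (is.finite(sc) &&
          (sc > best + 1e-12 ||
           (abs(sc - best) <= 1e-12 &&
            dx^2 + dy^2 < sum(best_d^2)))) {
        best <- sc
        best_d <- c(dx, dy)
      }
    }
  }
  list(dx = best_d[1], dy = best_d[2], score = best)
}

# Horizontal ribbon mask of odd width w centred vertically.
ribbon_mask <- function(h = 40, w = 80, width = 7) {
  m <- matrix(0L, h, w)
  mid <- h %/% 2
  half <- (width - 1) / 2
  m[(mid - half):(mid + half), 5:(w - 5)] <- 1L
  m
}

# Analytic kymograph: dark streaks of given slope (rows/column) on a flat
# background, optionally with Gaussian noise.
analytic_sta <- function(nr = 80, nt = 40, slope = 2, offsets = 40,
                         amp = 0.3, sd = 0, base = 0.6, widthRows = 3,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(base, nr, nt)
  for (t in seq_len(nt)) {
    for (o in offsets) {
      ctr <- o + slope * (t - 1)
      rows <- seq_len(nr)
      m[, t] <- m[, t] - amp * exp(-(rows - ctr)^2 / (2 * (widthRows / 2)^2))
    }
  }
  if (sd > 0) m <- m + matrix(rnorm(nr * nt, sd = sd), nr, nt)
  m
}

sta_from_matrix <- function(m, rowScaleUm = 0.908, fps = 25) {
  new("STAImage", matrix = m, rowScaleUm = rowScaleUm,
      colTimesS = (seq_len(ncol(m)) - 1) / fps, segmentId = 1)
}

# A small still scene (no motion artifacts) reused by several files.
still_scene <- function(seed = 7, n = 1, v = c(0.15, 0.15), ...) {
  renderScene(sceneConfig(seed = seed, nVessels = n, velocityRangeMms = v,
                          noiseSnr = Inf, blurFrames = integer(0),
                          saccades = list(), driftAmplitudePx = 0, ...))
}
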