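# Internal helpers. Image convention throughout: matrices indexed [row, col]
# with row = y increasing downward, col = x increasing rightward; a content
# displacement of (dx, dy) means the imaged tissue moved dx pixels right and
# dy pixels down between the reference frame and the current frame.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# EBImage stores images [x, y]; these wrappers keep the package in [row, col].
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

# Shift frame content by (dx, dy); vacated pixels take `fill`.
shift_frame <- function(m, dx, dy, fill = stats::median(m)) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# 3x3 convolution with replicated borders, via shift-and-add (vectorized).
conv3x3 <- function(m, k) {
  h <- nrow(m)
  w <- ncol(m)
  rpad <- rbind(m[1, , drop = FALSE], m, m[h, , drop = FALSE])
  p <- cbind(rpad[, 1, drop = FALSE], rpad, rpad[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (i in 1:3) {
    for (j in 1:3) {
      if (k[i, j] != 0)
        out <- out + k[i, j] * p[i:(i + h - 1), j:(j + w - 1)]
    }
  }
  out
}

sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (cols)
sobel_ky <- t(sobel_kx)                                          # d/dy (rows)

# separable Gaussian smoothing (reflect-free replicate borders)
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m)
  idx <- pmin(pmax(outer(seq_len(h), seq(-r, r), `+`), 1L), h)
  out <- matrix(0, h, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
  out
}

gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  t(convolve_rows(t(convolve_rows(m, k)), k))
}

# horizontal-ish linear motion-blur kernel of given length and angle (radians)
motion_blur_kernel <- function(len, angle = 0) {
  len <- max(1L, as.integer(round(len)))
  if (len == 1L) return(matrix(1, 1, 1))
  t_seq <- seq(-(len - 1) / 2, (len - 1) / 2, length.out = len)
  xs <- round(t_seq * cos(angle))
  ys <- round(t_seq * sin(angle))
  r <- max(abs(ys))
  c <- max(abs(xs))
  k <- matrix(0, 2 * r + 1, 2 * c + 1)
  for (i in seq_len(len)) {
    k[ys[i] + r + 1, xs[i] + c + 1] <- k[ys[i] + r + 1, xs[i] + c + 1] + 1
  }
  k / sum(k)
}

# arbitrary-size kernel convolution with replicate borders (small kernels)
conv_kernel <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  h <- nrow(m)
  w <- ncol(m)
  ridx <- pmin(pmax(seq(1 - kr, h + kr), 1L), h)
  cidx <- pmin(pmax(seq(1 - kc, w + kc), 1L), w)
  p <- m[ridx, cidx, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] != 0)
        out <- out + k[i, j] * p[i:(i + h - 1), j:(j + w - 1)]
    }
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
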