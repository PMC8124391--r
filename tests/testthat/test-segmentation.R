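test_that("preprocessing halves resolution and boosts vessel contrast", {
  x <- matrix(runif(1848 * 2208), 1848, 2208)
  y <- preprocessFrame(x)
  expect_equal(dim(y), c(924, 1104))

  # constant image: nothing to equalize
  z <- preprocessFrame(matrix(0.4, 100, 100), scale = 1)
  expect_equal(diff(range(z)), 0)

  # low-contrast synthetic vessel image: CLAHE raises Michelson contrast
  scene <- still_scene(seed = 51, v = c(0, 0), clusterContrast = 0)
  avg <- frames(scene)[, , 1]
  low <- 0.5 + 0.1 * (avg - 0.5)                      # squashed contrast
  pp <- preprocessFrame(low, scale = 1)
  michelson <- function(m) (max(m) - min(m)) / (max(m) + min(m))
  expect_gt(michelson(pp), michelson(low))

  # green channel from RGB input
  rgb <- array(0.2, c(64, 64, 3))
  rgb[, , 2] <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dim(preprocessFrame(rgb, scale = 1)), c(64, 64))
  expect_error(preprocessFrame("not an image"), "numeric")
})

test_that("patch extraction meets its size, normalization and determinism contracts", {
  set.seed(52)
  img <- matrix(runif(200 * 220), 200, 220)
  lab <- (img > 0.8) * 1
  ds <- extractPatches(img, lab, 40, seed = 9)
  expect_equal(dim(ds@patches), c(64, 64, 40))
  expect_true(all(ds@labels %in% c(0, 1)))
  expect_true(all(ds@provenance$size >= 64 & ds@provenance$size <= 128))

  mus <- apply(ds@patches, 3, mean)
  sds <- apply(ds@patches, 3, function(p) stats::sd(p))
  expect_lt(max(abs(mus)), 1e-6)
  expect_lt(max(abs(sds^2 - 1)), 1e-6)

  ds2 <- extractPatches(img, lab, 40, seed = 9)
  expect_identical(ds@patches, ds2@patches)
  expect_identical(ds@labels, ds2@labels)

  # a 64-px crop is passed through unresized (identity up to normalization)
  ds64 <- extractPatches(img, lab, 30, sizeRange = c(64, 64), seed = 3)
  i <- 1
  r0 <- ds64@provenance$row0[i]
  c0 <- ds64@provenance$col0[i]
  raw <- img[r0:(r0 + 63), c0:(c0 + 63)]
  expect_equal(ds64@patches[, , i], (raw - mean(raw)) / stats::sd(raw),
               tolerance = 1e-12)

  expect_error(extractPatches(img[1:100, 1:100], lab[1:100, 1:100], 5),
               "smaller")

  # constant patches normalize to zeros
  cds <- extractPatches(matrix(0.5, 150, 150), matrix(0, 150, 150), 5,
                        seed = 1)
  expect_true(all(cds@patches == 0))
})

test_that("augmentation applies geometry to both patch and label, blur to patch only", {
  patch <- matrix(0, 64, 64)
  patch[30:35, 10:55] <- 1
  lab <- patch

  idty <- augmentPatch(patch, lab, rotation = 0, shear = 0,
                       translation = c(0L, 0L), blur = FALSE)
  expect_equal(idty$patch, patch)
  expect_equal(idty$label, lab)

  r90 <- augmentPatch(patch, lab, rotation = 90, shear = FALSE,
                      translation = FALSE, blur = FALSE)
  ext <- which(r90$label == 1, arr.ind = TRUE)
  expect_equal(sum(r90$label), sum(lab))            # bar preserved exactly
  expect_gt(diff(range(ext[, 1])), diff(range(ext[, 2])))  # now vertical

  set.seed(53)
  blr <- augmentPatch(patch, lab, rotation = FALSE, shear = FALSE,
                      translation = FALSE, blur = 7)
  expect_equal(blr$label, lab)                      # label untouched by blur
  expect_false(identical(blr$patch, patch))
  expect_equal(sum(blr$patch), sum(patch), tolerance = 0.05 * sum(patch))

  tr <- augmentPatch(patch, lab, rotation = FALSE, shear = FALSE,
                     translation = c(5L, -3L), blur = FALSE)
  expect_equal(sum(tr$label), sum(lab[, ]))         # fully inside, preserved
})

test_that("the Dice coefficient satisfies its identities", {
  a <- matrix(0, 10, 10)
  a[3:6, 3:6] <- 1
  expect_equal(diceCoefficient(a, a), 1, tolerance = 1e-5)

  b <- matrix(0, 10, 10)
  b[8:9, 8:9] <- 1
  expect_equal(diceCoefficient(a, b), 0, tolerance = 1e-5)

  bar <- matrix(0, 4, 20)
  bar[2, 1:10] <- 1
  shifted <- matrix(0, 4, 20)
  shifted[2, 6:15] <- 1
  expect_equal(diceCoefficient(bar, shifted), 0.5, tolerance = 1e-5)

  set.seed(54)
  p <- matrix(runif(100), 10, 10)
  q <- (matrix(runif(100), 10, 10) > 0.5) * 1
  expect_equal(diceCoefficient(p, q), diceCoefficient(q, p))
  expect_gte(diceCoefficient(p, q), 0)
  expect_lte(diceCoefficient(p, q), 1)
  expect_equal(diceCoefficient(matrix(0, 5, 5), matrix(0, 5, 5)), 1)

  expect_error(diceCoefficient(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("multiscale vesselness segments clean synthetic scenes at Dice >= 0.7", {
  scene <- still_scene(seed = 55, n = 3, v = c(0.1, 0.3))
  avg <- apply(frames(scene)[, , 1:30], c(1, 2), mean)
  mask <- segmentVesselness(preprocessFrame(avg, scale = 1))
  expect_gte(diceCoefficient(mask, groundTruth(scene)$mask), 0.7)
})

test_that("vesselness responds to dark curvilinear structures, not blobs", {
  img <- matrix(0.8, 80, 80)
  img[40:42, 10:70] <- 0.4                           # a dark line
  v <- frangiVesselness(img)
  line_resp <- mean(v[41, 20:60])
  img2 <- matrix(0.8, 80, 80)
  img2[38:44, 38:44] <- 0.4                          # a dark blob
  v2 <- frangiVesselness(img2)
  expect_gt(line_resp, 2 * v2[41, 41])
  # bright line on dark background: wrong polarity, suppressed
  img3 <- 1 - img
  v3 <- frangiVesselness(img3)
  expect_lt(mean(v3[41, 20:60]), 0.1 * line_resp)
})
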