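test_that("skeletonization thins ribbons to single-pixel chains and is idempotent", {
  m <- ribbon_mask(31, 80, 5)
  sk <- skeletonize(m)
  nc <- neighborCount(sk)
  expect_true(all(nc[sk == 1] <= 2))                 # a simple chain
  rows <- which(sk == 1, arr.ind = TRUE)[, 1]
  mid <- 31 %/% 2
  expect_true(all(abs(rows - mid) <= 2))             # near the medial axis
  expect_identical(skeletonize(sk), sk)

  expect_equal(sum(skeletonize(matrix(0L, 10, 10))), 0)
})

test_that("a synthetic Y-vessel skeleton contains exactly one bifurcation", {
  m <- matrix(0L, 60, 60)
  # three 5-px-wide arms meeting at (30, 30)
  stamp <- function(r0, c0, r1, c1) {
    n <- 80
    rr <- round(seq(r0, r1, length.out = n))
    cc <- round(seq(c0, c1, length.out = n))
    for (i in seq_len(n)) {
      m[max(1, rr[i] - 2):min(60, rr[i] + 2),
        max(1, cc[i] - 2):min(60, cc[i] + 2)] <<- 1L
    }
  }
  stamp(30, 30, 30, 5)
  stamp(30, 30, 8, 50)
  stamp(30, 30, 52, 50)
  sk <- skeletonize(m)
  jx <- classifyJunctions(sk)
  expect_equal(nrow(jx$bifurcations), 1)
  expect_equal(nrow(jx$crossovers), 0)
})

test_that("neighbour counts follow the 3x3 window rule", {
  line <- matrix(0L, 5, 9)
  line[3, 2:8] <- 1L
  nc <- neighborCount(line)
  expect_equal(nc[3, 5], 2)          # interior chain pixel
  expect_equal(nc[3, 2], 1)          # endpoint
  plus <- matrix(0L, 9, 9)
  plus[5, 2:8] <- 1L
  plus[2:8, 5] <- 1L
  expect_equal(neighborCount(plus)[5, 5], 4)

  # sum over a simple open chain of n pixels is 2(n - 1)
  for (n in c(5, 12, 30)) {
    chain <- matrix(0L, 3, n + 2)
    chain[2, 2:(n + 1)] <- 1L
    expect_equal(sum(neighborCount(chain)), 2 * (n - 1))
  }
  diag_chain <- diag(1L, 15)
  expect_equal(sum(neighborCount(diag_chain)), 2 * 14)
})

test_that("bifurcations count three neighbours, crossovers more", {
  # fixtures are skeletonized first: the junction rule is defined on
  # minimally thin skeletons
  tee <- matrix(0L, 9, 9)
  tee[5, 2:8] <- 1L
  tee[6:8, 5] <- 1L
  jt <- classifyJunctions(skeletonize(tee))
  expect_equal(nrow(jt$bifurcations), 1)
  expect_equal(nrow(jt$crossovers), 0)

  plus <- matrix(0L, 9, 9)
  plus[5, 2:8] <- 1L
  plus[2:8, 5] <- 1L
  jp <- classifyJunctions(skeletonize(plus))
  expect_equal(nrow(jp$bifurcations), 0)
  # the centre reads as a crossover; in 8-connectivity its four arm
  # neighbours also exceed three neighbours and join the junction cluster
  expect_gte(nrow(jp$crossovers), 1)
  expect_true(any(jp$crossovers[, 1] == 5 & jp$crossovers[, 2] == 5))

  line <- matrix(0L, 5, 20)
  line[3, 2:19] <- 1L
  jl <- classifyJunctions(line)
  expect_equal(nrow(jl$bifurcations) + nrow(jl$crossovers), 0)
})

test_that("segment extraction prunes below 20 px and orders chains", {
  line30 <- matrix(0L, 5, 34)
  line30[3, 3:32] <- 1L
  g <- extractSegments(line30)
  expect_length(segments(g), 1)
  expect_equal(segments(g)[[1]]$lengthPx, 30)
  px <- segments(g)[[1]]$pixels
  expect_equal(px[1, ], c(row = 3, col = 3))         # starts at smaller end
  expect_true(all(diff(px[, 2]) == 1))               # ordered walk

  line15 <- matrix(0L, 5, 20)
  line15[3, 3:17] <- 1L
  expect_length(segments(extractSegments(line15)), 0)

  line20 <- matrix(0L, 5, 26)
  line20[3, 3:22] <- 1L
  expect_length(segments(extractSegments(line20)), 1)
})

test_that("a Y of three 25-px arms separates into three segments", {
  y <- matrix(0L, 60, 60)
  y[30, 5:30] <- 1L                                  # west arm
  for (k in 0:25) {
    y[30 - k, 30 + k] <- 1L                          # north-east arm
    y[30 + k, 30 + k] <- 1L                          # south-east arm
  }
  sk <- skeletonize(y)
  g <- extractSegments(sk)
  expect_length(segments(g), 3)
  lens <- sort(vapply(segments(g), `[[`, numeric(1), "lengthPx"))
  expect_true(all(lens >= 23 & lens <= 27))
})

test_that("diameters from the distance transform are exact on odd-width ribbons", {
  for (w in seq(3, 15, 2)) {
    m <- ribbon_mask(41, 80, w)
    g <- vesselGraph(m)
    expect_length(segments(g), 1)
    expect_equal(segments(g)[[1]]$diameterPx, w,
                 info = sprintf("width %d", w))
  }
  # 1-px line as its own mask: d = 1, diameter 1
  one <- matrix(0L, 5, 30)
  one[3, 2:29] <- 1L
  g1 <- measureDiameters(extractSegments(skeletonize(one)), one)
  expect_equal(segments(g1)[[1]]$diameterPx, 1)
})

test_that("synthetic vessel diameters and lengths are recovered from the mask", {
  cfg <- sceneConfig(seed = 31, nVessels = 1, diameterRangeUm = c(10, 10))
  v <- generateVessels(cfg)
  g <- vesselGraph(v$mask)
  expect_length(segments(g), 1)
  expect_equal(segments(g)[[1]]$diameterPx, v$diametersPx[1], tolerance = 0.15)
  # physical length within 10% of the generator's arc length
  arc <- max(v$centerlines[[1]][, "s"])
  expect_equal(segments(g)[[1]]$lengthPx, arc, tolerance = 0.1)
})

test_that("centerline pixels on background raise an inconsistency error", {
  m <- ribbon_mask(41, 80, 7)
  g <- extractSegments(skeletonize(m))
  expect_error(measureDiameters(g, m * 0), "background")
})

test_that("segment label image carries ids at centerline pixels", {
  m <- ribbon_mask(41, 80, 7)
  g <- vesselGraph(m)
  lab <- segmentLabelImage(g)
  expect_setequal(unique(lab[lab > 0]), 1L)
  expect_equal(sum(lab > 0), segments(g)[[1]]$lengthPx)
})
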