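test_that("observability ranks flowing vessels above static ones of equal length", {
  scene <- renderScene(sceneConfig(seed = 41, nVessels = 2,
                                   velocityRangeMms = c(0.2, 0.2),
                                   noiseSnr = Inf, blurFrames = integer(0),
                                   saccades = list(), driftAmplitudePx = 0))
  gt <- groundTruth(scene)
  g <- vesselGraph(gt$mask)
  # rebuild the scene with one vessel's flow switched off by zero contrast:
  # instead, compare sigmaT of a static sequence against the flowing one
  rk <- observabilityRank(scene@sequence, g, k = 15)
  expect_equal(rk@table$index, sort(rk@table$index, decreasing = TRUE))
  expect_true(all(rk@table$sigmaT >= 0))

  # alpha = 0 reduces to pure length ordering
  rk_len <- observabilityRank(scene@sequence, g, alpha = 0, beta = 1)
  lens <- rk_len@table$lengthPx
  expect_equal(lens, sort(lens, decreasing = TRUE))

  one <- scene@sequence[1]
  expect_error(observabilityRank(one, g), "at least 2")
})

test_that("flowing vessels outrank static vessels in a mixed scene", {
  # render flowing and static vessels as separate scenes on disjoint layouts,
  # then combine frame stacks side by side
  flow <- renderScene(sceneConfig(seed = 42, nVessels = 2, width = 200,
                                  height = 200,
                                  velocityRangeMms = c(0.25, 0.25),
                                  noiseSnr = Inf, blurFrames = integer(0),
                                  saccades = list(), driftAmplitudePx = 0))
  still <- renderScene(sceneConfig(seed = 43, nVessels = 2, width = 200,
                                   height = 200, velocityRangeMms = c(0, 0),
                                   noiseSnr = Inf, blurFrames = integer(0),
                                   saccades = list(), driftAmplitudePx = 0))
  fr <- array(0, c(200, 400, 30))
  fr[, 1:200, ] <- frames(flow)[, , 1:30]
  fr[, 201:400, ] <- frames(still)[, , 1:30]
  sq <- frameSequence(fr, micronsPerPixel = 0.908)
  mask <- cbind(groundTruth(flow)$mask, groundTruth(still)$mask)
  g <- vesselGraph(mask)
  rk <- observabilityRank(sq, g, k = 2)
  flow_ids <- vapply(segments(g), function(s) any(s$pixels[, 2] <= 200),
                     logical(1))
  top <- rk@selectedIds
  expect_true(all(top %in% which(flow_ids)))
})

test_that("STA images stack centerline intensities column by column", {
  scene <- still_scene(seed = 44, v = c(0, 0))
  g <- vesselGraph(groundTruth(scene)$mask)
  sta <- buildSTA(scene@sequence, segments(g)[[1]])
  expect_equal(dim(staMatrix(sta)),
               c(segments(g)[[1]]$lengthPx, nFrames(scene@sequence)))
  # static scene: all columns identical
  m <- staMatrix(sta)
  expect_equal(max(apply(m, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-12)
  expect_equal(sta@colTimesS, frameTimes(scene@sequence))

  bad <- segments(g)[[1]]
  bad$pixels[1, ] <- c(10000L, 1L)
  expect_error(buildSTA(scene@sequence, bad), "bounds")
})

test_that("streak slopes are recovered from analytic kymographs", {
  sta <- sta_from_matrix(analytic_sta(nr = 80, nt = 40, slope = 2,
                                      offsets = c(10, 40)))
  sl <- estimateSlopes(sta)
  expect_gt(length(sl$slopes), 0)
  expect_equal(unique(round(abs(sl$slopes), 2)), 2, tolerance = 0.025)

  # two parallel streaks of slope 1.5 are both found
  sta2 <- sta_from_matrix(analytic_sta(nr = 60, nt = 40, slope = 1.5,
                                       offsets = c(5, 30)))
  sl2 <- estimateSlopes(sta2)
  expect_gte(length(sl2$slopes), 2)
  expect_true(all(abs(abs(sl2$slopes) - 1.5) <= 0.05))

  # pure noise yields no streaks
  set.seed(45)
  noise <- matrix(rnorm(80 * 40, sd = 0.05), 80, 40) + 0.5
  expect_length(estimateSlopes(sta_from_matrix(noise))$slopes, 0)
})

test_that("slopes survive noise at one tenth of the streak contrast", {
  sta <- sta_from_matrix(analytic_sta(nr = 100, nt = 60, slope = 3,
                                      offsets = c(10, 45, 80), amp = 0.3,
                                      sd = 0.03, seed = 46))
  sl <- estimateSlopes(sta)
  expect_gt(length(sl$slopes), 0)
  expect_equal(mean(abs(sl$slopes)), 3, tolerance = 0.05)
})

test_that("slope-to-velocity conversion uses the optical scale and frame times", {
  sta <- sta_from_matrix(analytic_sta(slope = 2), rowScaleUm = 0.90837,
                         fps = 25)
  est <- velocityFromSlopes(2, sta)
  expect_equal(est@velocityMmS, 2 * 0.90837 * 25 / 1000, tolerance = 1e-12)
  expect_equal(est@velocityMmS, 0.0454, tolerance = 1e-3)

  expect_equal(velocityFromSlopes(0, sta)@velocityMmS, 0)
  none <- velocityFromSlopes(numeric(0), sta)
  expect_true(is.na(none@velocityMmS))
  expect_equal(none@nStreaks, 0)

  # sign is discarded
  expect_equal(velocityFromSlopes(-2, sta)@velocityMmS,
               velocityFromSlopes(2, sta)@velocityMmS)
})

test_that("velocity is invariant to global intensity scaling", {
  scene <- still_scene(seed = 47, v = c(0.2, 0.2))
  g <- vesselGraph(groundTruth(scene)$mask)
  v1 <- measureVelocities(scene@sequence, g, k = 1)$velocity_mm_s
  dim_seq <- frameSequence(frames(scene) * 0.5, fps = 25,
                           micronsPerPixel = 0.908)
  v2 <- measureVelocities(dim_seq, g, k = 1)$velocity_mm_s
  expect_equal(v1, v2, tolerance = 0.02)
})

test_that("doubling fps while halving per-frame displacement preserves velocity", {
  base <- analytic_sta(nr = 90, nt = 30, slope = 2, offsets = c(10, 50))
  fast <- analytic_sta(nr = 90, nt = 60, slope = 1, offsets = c(10, 50))
  v1 <- velocityFromSlopes(estimateSlopes(sta_from_matrix(base, fps = 25))$slopes,
                           sta_from_matrix(base, fps = 25))@velocityMmS
  v2 <- velocityFromSlopes(estimateSlopes(sta_from_matrix(fast, fps = 50))$slopes,
                           sta_from_matrix(fast, fps = 50))@velocityMmS
  expect_equal(v1, v2, tolerance = 0.02 * v1)
})

test_that("a moving dark blob advances through STA rows at its known rate", {
  scene <- still_scene(seed = 48, v = c(0.2, 0.2))
  gt <- groundTruth(scene)
  g <- vesselGraph(gt$mask)
  sta <- buildSTA(scene@sequence, segments(g)[[1]])
  sl <- estimateSlopes(sta)
  expect_gt(length(sl$slopes), 0)
  expect_equal(mean(abs(sl$slopes)), gt$velocitiesPxPerFrame[1],
               tolerance = 0.1 * gt$velocitiesPxPerFrame[1])
})
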