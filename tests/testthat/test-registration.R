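test_that("contrast index matches a hand-convolved Sobel oracle and detects blur", {
  expect_equal(contrastIndex(matrix(0.7, 12, 12)), 0)

  set.seed(4)
  frame <- matrix(runif(64), 8, 8)
  expect_equal(contrastIndex(frame), oracle_sobel_mean(frame),
               tolerance = 1e-12)

  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  expect_equal(contrastIndex(step), oracle_sobel_mean(step),
               tolerance = 1e-12)

  sharp <- matrix(runif(64 * 64), 64, 64)
  blurred <- conjuflow:::gaussian_blur(sharp, 2)
  expect_gt(contrastIndex(sharp), contrastIndex(blurred))

  expect_error(contrastIndex(matrix(1, 2, 2)), "3 x 3")
})

test_that("contrast index is additive-invariant and multiplicatively linear", {
  set.seed(5)
  f <- matrix(runif(400), 20, 20)
  ci <- contrastIndex(f)
  expect_equal(contrastIndex(f + 0.3), ci, tolerance = 1e-10)
  expect_equal(contrastIndex(2.5 * f), 2.5 * ci, tolerance = 1e-10)
})

test_that("frame selection keeps the 95% band and the sharpest template", {
  # force known indices by scaling one noisy frame pattern
  set.seed(6)
  base <- matrix(runif(900), 30, 30)
  amps <- c(10, 9.6, 9.4, 5) / 10
  seqs <- frameSequence(array(unlist(lapply(amps, function(a) a * base)),
                              c(30, 30, 4)))
  rep <- selectFrames(seqs)
  expect_equal(rep@threshold, 0.95 * max(rep@indexPerFrame))
  expect_equal(keptIndices(rep), c(1L, 2L))
  expect_equal(templateIndex(rep), 1L)

  # all-equal indices: everything kept, earliest frame is the template
  eq <- frameSequence(array(rep(base, 3), c(30, 30, 3)))
  repq <- selectFrames(eq)
  expect_equal(keptIndices(repq), 1:3)
  expect_equal(templateIndex(repq), 1L)

  # single frame
  one <- frameSequence(array(base, c(30, 30, 1)))
  expect_equal(keptIndices(selectFrames(one)), 1L)
})

test_that("deliberately blurred frames of a synthetic scene are exactly rejected", {
  scene <- renderScene(sceneConfig(seed = 21, nFrames = 30,
                                   blurFrames = c(4, 11, 27)))
  rep <- selectFrames(scene@sequence)
  expect_setequal(setdiff(1:30, keptIndices(rep)), c(4, 11, 27))
})

test_that("integer translations are recovered exactly", {
  scene <- still_scene(seed = 9)
  f <- frames(scene)[, , 1]
  shifted <- conjuflow:::shift_frame(f, 5, -3)
  s <- estimateShift(f, shifted, searchRadius = 20)
  expect_equal(c(s$dx, s$dy), c(5L, -3L))
  self <- estimateShift(f, f, searchRadius = 20)
  expect_equal(c(self$dx, self$dy), c(0L, 0L))
  expect_error(estimateShift(f[1:10, 1:10], f[1:10, 1:10],
                             searchRadius = 12), "search radius")
})

test_that("pyramid shift search agrees with the exhaustive oracle on small frames", {
  set.seed(10)
  for (i in 1:5) {
    ref <- matrix(runif(64 * 64), 64, 64)
    ref <- conjuflow:::gaussian_blur(ref, 1.5)   # correlated texture
    d <- sample(-6:6, 2)
    mov <- conjuflow:::shift_frame(ref, d[1], d[2], fill = mean(ref))
    got <- estimateShift(ref, mov, searchRadius = 8)
    want <- oracle_best_shift(ref, mov, 8)
    expect_equal(c(got$dx, got$dy), c(want$dx, want$dy))
  }
})

test_that("registration recovers synthetic jitter exactly and is idempotent", {
  scene <- renderScene(sceneConfig(seed = 13, nFrames = 20,
                                   blurFrames = integer(0)))
  gt <- groundTruth(scene)
  rep <- selectFrames(scene@sequence)
  reg <- registerTranslation(scene@sequence, rep, searchRadius = 64)
  kept <- keptIndices(rep)
  true_rel <- sweep(gt$displacements[kept, , drop = FALSE], 2,
                    gt$displacements[templateIndex(rep), ])
  expect_equal(unname(displacements(reg)), unname(true_rel))

  # re-registering the corrected output finds nothing left to correct
  rep2 <- selectFrames(reg@registered)
  reg2 <- registerTranslation(reg@registered, rep2, searchRadius = 64)
  expect_true(all(displacements(reg2) == 0))
})

test_that("noisy registration stays within one pixel of ground truth", {
  scene <- renderScene(sceneConfig(seed = 14, nFrames = 20, noiseSnr = 10,
                                   blurFrames = integer(0)))
  gt <- groundTruth(scene)
  rep <- selectFrames(scene@sequence)
  reg <- registerTranslation(scene@sequence, rep, searchRadius = 64)
  kept <- keptIndices(rep)
  true_rel <- sweep(gt$displacements[kept, , drop = FALSE], 2,
                    gt$displacements[templateIndex(rep), ])
  expect_lte(max(abs(displacements(reg) - true_rel)), 1)
})
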