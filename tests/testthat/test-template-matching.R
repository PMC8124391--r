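make_measured_graph <- function() {
  m <- matrix(0L, 80, 120)
  m[18:24, 10:110] <- 1L        # long, 7 px wide
  m[50:60, 30:80] <- 1L         # shorter, 11 px wide
  vesselGraph(m)
}

test_that("template vessel selection weighs normalized length and diameter", {
  g <- make_measured_graph()
  f <- matrix(runif(80 * 120), 80, 120)
  sel <- selectTemplateVessel(g, f)
  # equal weights: min-max normalization gives both segments score 0.5;
  # the tie breaks to the lower id (the longer vessel, traced first)
  expect_equal(sel@scores$score, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sel@chosenSegmentId, 1)

  long_only <- selectTemplateVessel(g, f, w1 = 1, w2 = 0)
  lens <- vapply(segments(g), `[[`, numeric(1), "lengthPx")
  expect_equal(long_only@chosenSegmentId,
               segments(g)[[which.max(lens)]]$id)

  wide_only <- selectTemplateVessel(g, f, w1 = 0, w2 = 1)
  dias <- vapply(segments(g), `[[`, numeric(1), "diameterPx")
  expect_equal(wide_only@chosenSegmentId,
               segments(g)[[which.max(dias)]]$id)

  # a single segment trivially wins with full score
  m1 <- ribbon_mask(41, 80, 7)
  g1 <- vesselGraph(m1)
  s1 <- selectTemplateVessel(g1, matrix(runif(41 * 80), 41, 80))
  expect_equal(s1@scores$score, 1)

  expect_error(selectTemplateVessel(g, f, w1 = 0.7, w2 = 0.5), "equal 1")
})

test_that("template crop covers the chosen vessel with its margin", {
  g <- make_measured_graph()
  f <- matrix(runif(80 * 120), 80, 120)
  sel <- selectTemplateVessel(g, f, margin = 5)
  seg <- segments(g)[[sel@chosenSegmentId]]
  box <- sel@box
  expect_true(all(seg$pixels[, 1] >= box[1] &
                  seg$pixels[, 1] <= box[1] + box[3] - 1))
  expect_true(all(seg$pixels[, 2] >= box[2] &
                  seg$pixels[, 2] <= box[2] + box[4] - 1))
  expect_equal(dim(sel@templateImage), box[3:4])
})

test_that("normalized correlation matching recovers exact placements", {
  set.seed(17)
  frame <- matrix(runif(40 * 40), 40, 40) + 0.2
  tpl <- frame[11:18, 21:30]
  m <- matchTemplate(frame, tpl, refPos = c(11L, 21L))
  expect_equal(c(m$dx, m$dy), c(0L, 0L))
  expect_equal(m$peak, 1, tolerance = 1e-12)

  shifted <- conjuflow:::shift_frame(frame, 2, 1, fill = mean(frame))
  m2 <- matchTemplate(shifted, tpl, refPos = c(11L, 21L))
  expect_equal(c(m2$dx, m2$dy), c(2L, 1L))

  expect_error(matchTemplate(tpl, frame), "smaller")
  expect_error(matchTemplate(frame, matrix(0, 4, 4)), "flat")
})

test_that("the correlation map equals the brute-force definition everywhere", {
  set.seed(18)
  for (i in 1:20) {
    img <- matrix(runif(32 * 32), 32, 32)
    tpl <- matrix(runif(64), 8, 8)
    got <- matchTemplate(img, tpl)$scores
    want <- oracle_ncc_map(img, tpl)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("matching is invariant to positive scaling of the frame", {
  set.seed(19)
  img <- matrix(runif(900), 30, 30)
  tpl <- img[5:12, 8:17]
  a <- matchTemplate(img, tpl)
  b <- matchTemplate(3.7 * img, tpl)
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
})

test_that("fine correction removes injected drift and leaves still video alone", {
  scene <- still_scene(seed = 23, n = 1, v = c(0, 0))
  f <- frames(scene)[, , 1]
  drift <- rbind(c(0, 0), c(2, -1), c(-3, 2), c(1, 3), c(0, -2))
  fr <- array(0, c(dim(f), nrow(drift)))
  for (i in seq_len(nrow(drift))) {
    fr[, , i] <- conjuflow:::shift_frame(f, drift[i, 1], drift[i, 2])
  }
  sq <- frameSequence(fr, micronsPerPixel = 0.908)
  g <- vesselGraph(groundTruth(scene)$mask)
  sel <- selectTemplateVessel(g, f)
  fc <- correctSequence(sq, sel)
  expect_equal(unname(displacements(fc)), unname(drift))
  # corrected content matches the reference frame away from the filled border
  expect_equal(fc@corrected@frames[30:100, 30:100, 3], f[30:100, 30:100])

  still <- frameSequence(array(rep(f, 4), c(dim(f), 4)),
                         micronsPerPixel = 0.908)
  fc0 <- correctSequence(still, sel)
  expect_true(all(displacements(fc0) == 0))
  expect_equal(fc0@corrected@frames, still@frames)
})

test_that("frames with poor template correlation are flagged", {
  scene <- still_scene(seed = 23, n = 1, v = c(0, 0))
  f <- frames(scene)[, , 1]
  noise <- matrix(runif(length(f)), nrow(f), ncol(f))
  sq <- frameSequence(array(c(f, noise), c(dim(f), 2)),
                      micronsPerPixel = 0.908)
  g <- vesselGraph(groundTruth(scene)$mask)
  sel <- selectTemplateVessel(g, f)
  expect_warning(fc <- correctSequence(sq, sel, minCorr = 0.5,
                                       zeroMean = TRUE),
                 "correlation floor")
  expect_false(fc@flagged[1])
  expect_true(fc@flagged[2])
})
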