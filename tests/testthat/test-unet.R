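ns <- asNamespace("conjuflow")

test_that("parameter count matches layer-by-layer arithmetic", {
  f <- 8
  conv <- function(cin, cout) 9 * cin * cout + 2 * cout     # weights + BN
  gate <- function(cs) {
    fi <- cs %/% 2
    2 * cs * fi + fi + fi + 1                               # Wx, Wg, bg, Wp, bp
  }
  expected <- conv(1, f) + conv(f, f) +
    conv(f, 2 * f) + conv(2 * f, 2 * f) +
    conv(2 * f, 4 * f) + conv(4 * f, 4 * f) +
    conv(4 * f, 8 * f) + conv(8 * f, 8 * f) +
    conv(8 * f, 4 * f) + gate(4 * f) + conv(8 * f, 4 * f) + conv(4 * f, 4 * f) +
    conv(4 * f, 2 * f) + gate(2 * f) + conv(4 * f, 2 * f) + conv(2 * f, 2 * f) +
    conv(2 * f, f) + gate(f) + conv(2 * f, f) + conv(f, f) +
    (f * 2 + 2)                                             # softmax head
  model <- buildUNet(unetSpec(baseFilters = f), seed = 1)
  expect_equal(countParams(model), expected)
})

test_that("the network maps patches to per-pixel vessel probabilities", {
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 2)
  unet_fw <- get("unet_fw", ns)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- unet_fw(model@params, model@state, x, training = FALSE)
  expect_equal(dim(fw$prob), c(64, 64, 3))
  expect_true(all(fw$prob > 0 & fw$prob < 1))       # two-class softmax
})

test_that("attention coefficients are sigmoid-bounded in [0, 1]", {
  gate_fw <- get("gate_fw", ns)
  new_gate <- get("new_gate", ns)
  set.seed(3)
  layer <- new_gate(4L, 4L)
  s <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  g <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  r <- gate_fw(s, g, layer)
  expect_true(all(r$alpha >= 0 & r$alpha <= 1))
  # gated output is the skip attenuated by alpha
  expect_true(all(abs(r$y) <= abs(s) + 1e-12))
})

test_that("an untrained net is translation-equivariant at pooling granularity", {
  # the canvas must exceed the receptive field so an interior region exists
  # that never sees the zero-padded borders
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 4)
  unet_fw <- get("unet_fw", ns)
  set.seed(5)
  n <- 160
  img <- matrix(0, n, n)
  img[72:78, 30:130] <- 1                            # a bar
  img <- img + matrix(rnorm(n * n, sd = 0.05), n, n)
  sh <- rbind(matrix(0, 8, n), img[1:(n - 8), ])     # shift down by 8 px
  x <- array(c(img, sh), c(n, n, 2, 1))
  fw <- unet_fw(model@params, model@state, x, training = FALSE)
  inner_r <- 65:96
  inner_c <- 57:104
  expect_equal(fw$prob[inner_r, inner_c, 2],
               fw$prob[inner_r - 8, inner_c, 1], tolerance = 1e-6)
})

test_that("analytic gradients match numerical differences", {
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 6)
  unet_fw <- get("unet_fw", ns)
  unet_bw <- get("unet_bw", ns)
  dlg <- get("dice_loss_grad", ns)
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  q <- array((runif(8 * 8 * 2) > 0.6) * 1, c(8, 8, 2))
  p <- model@params
  lossfn <- function(pp) {
    dlg(unet_fw(pp, model@state, x, TRUE)$prob, q)$loss
  }
  fw <- unet_fw(p, model@state, x, TRUE)
  g <- unet_bw(p, fw$caches, dlg(fw$prob, q)$dprob)
  base <- lossfn(p)
  eps <- 1e-6
  check <- list(c("enc1_1_conv", "W"), c("bot_2_conv", "W"),
                c("att2", "Wx"), c("up1_conv", "W"),
                c("dec1_2_bn", "gamma"), c("head", "W"))
  for (ch in check) {
    arr <- p[[ch[1]]][[ch[2]]]
    for (i in sample(length(arr), 2)) {
      p2 <- p
      p2[[ch[1]]][[ch[2]]][i] <- p2[[ch[1]]][[ch[2]]][i] + eps
      num <- (lossfn(p2) - base) / eps
      ana <- g[[ch[1]]][[ch[2]]][i]
      expect_equal(ana, num, tolerance = 2e-3,
                   info = paste(ch, collapse = "$"))
    }
  }
})

test_that("the train/validation split follows the 4:1 ratio", {
  expect_equal(patchSplit(300000), c(train = 240000, val = 60000))
  expect_equal(patchSplit(2000), c(train = 1600, val = 400))
  expect_equal(sum(patchSplit(12345)), 12345)
})

test_that("learning-rate-on-plateau reduces by 1/10 after the patience window", {
  set.seed(8)
  # a learning rate too small to produce measurable improvement forces a
  # plateau, so the schedule must fire every `patience` epochs
  patches <- array(rnorm(64 * 64 * 10), c(64, 64, 10))
  labels <- array((runif(64 * 64 * 10) > 0.8) * 1, c(64, 64, 10))
  ds <- new("PatchDataset", patches = patches, labels = labels,
            provenance = data.frame(source = 1:10, row0 = 1, col0 = 1,
                                    size = 64, augmented = ""))
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 9)
  tm <- trainUNet(model, ds, trainConfig(epochs = 5, lr = 1e-13,
                                         patience = 2, batchSize = 5,
                                         seed = 1))
  lrs <- tm@history$lr
  expect_equal(lrs[2], 1e-13)          # first stall epoch, no drop yet
  expect_equal(lrs[3], 1e-14)          # patience reached -> factor 0.1
  expect_equal(lrs[5], 1e-15)          # and again after two more stalls
})

test_that("a short training run reduces the Dice loss on an easy task", {
  set.seed(10)
  # dark bars on bright background, labels = the bars
  n <- 24
  patches <- array(0, c(64, 64, n))
  labels <- array(0, c(64, 64, n))
  for (i in seq_len(n)) {
    p <- matrix(0.8, 64, 64)
    r <- sample(10:50, 1)
    p[r:(r + 4), ] <- 0.3
    labels[r:(r + 4), , i] <- 1
    patches[, , i] <- (p - mean(p)) / sd(p)
  }
  ds <- new("PatchDataset", patches = patches, labels = labels,
            provenance = data.frame(source = seq_len(n), row0 = 1, col0 = 1,
                                    size = 64, augmented = ""))
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 11)
  tm <- trainUNet(model, ds, trainConfig(epochs = 8, lr = 3e-3,
                                         patience = 6, batchSize = 8,
                                         seed = 2))
  h <- tm@history
  expect_lt(h$train_loss[8], h$train_loss[1])
  expect_lt(min(h$val_loss), min(0.6, h$val_loss[1]))
})

test_that("full-image prediction returns a binary mask at the working size", {
  model <- buildUNet(unetSpec(baseFilters = 2), seed = 12)
  img <- matrix(runif(96 * 130), 96, 130)
  mask <- predictMask(model, img, preprocess = FALSE)
  expect_equal(dim(mask), c(96, 130))
  expect_true(all(mask %in% c(0L, 1L)))

  # sequences shorter than averageN warn and use all frames
  sq <- frameSequence(array(runif(96 * 96 * 5), c(96, 96, 5)))
  expect_warning(m2 <- predictMask(model, sq, averageN = 30,
                                   preprocess = FALSE), "averaging all")
  expect_equal(dim(m2), c(96, 96))
})
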