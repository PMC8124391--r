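#' @include AllClasses.R AllGenerics.R utils.R segmentation.R
NULL

# A compact attention U-Net implemented directly on im2col/GEMM primitives:
# three encoder stages (two 3x3 conv + batch-norm + ReLU each, 2x2 max-pool
# between), a bottom stage, and three decoder stages (3x3 stride-2 transposed
# convolution, an additive attention gate on the skip connection,
# concatenation, two conv blocks), finished by a 1x1 convolution and a
# two-class softmax. Trained with Adam on a Dice loss.
#
# Activations are arrays (H, W, B, C), channels last, so reshaping to an
# (N x C) matrix for GEMM needs no permutation. Transposed convolution is the
# direct stride-2 scatter form (no zero-interleaving is materialized).

#' Specify the attention U-Net architecture
#'
#' @param stages number of encoder/decoder stages (fixed at 3).
#' @param baseFilters filters in the first stage; doubled at each deeper
#'   stage (default 32, i.e. 32/64/128 with 256 at the bottom).
#' @return list describing the architecture.
#' @export
unetSpec <- function(stages = 3, baseFilters = 32) {
  if (stages != 3) stopf("this implementation fixes the stage count at 3")
  list(stages = 3L, baseFilters = as.integer(baseFilters))
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

new_conv <- function(cin, cout) {
  list(W = he_init(9 * cin, cout))      # no bias: batch-norm follows
}

new_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

new_gate <- function(cs, cg) {
  fi <- max(1L, cs %/% 2L)
  list(Wx = he_init(cs, fi), Wg = he_init(cg, fi), bg = numeric(fi),
       Wp = he_init(fi, 1), bp = 0)
}

#' Build an untrained attention U-Net
#'
#' @param spec architecture from [unetSpec()].
#' @param seed RNG seed for the He-normal weight initialization.
#' @return an untrained [UNetModel-class].
#' @export
buildUNet <- function(spec = unetSpec(), seed = 1) {
  withr::local_seed(seed)
  f <- spec$baseFilters
  p <- list()
  s <- list()
  add_block <- function(p, s, name, cin, cout) {
    p[[paste0(name, "_conv")]] <- new_conv(cin, cout)
    p[[paste0(name, "_bn")]] <- new_bn(cout)
    s[[paste0(name, "_bn")]] <- list(mean = numeric(cout),
                                     var = rep(1, cout), n = 0)
    list(p = p, s = s)
  }
  chans <- c(f, 2 * f, 4 * f)
  cin <- 1L
  for (st in 1:3) {
    for (cv in 1:2) {
      r <- add_block(p, s, sprintf("enc%d_%d", st, cv), cin, chans[st])
      p <- r$p; s <- r$s
      cin <- chans[st]
    }
  }
  r <- add_block(p, s, "bot_1", 4 * f, 8 * f); p <- r$p; s <- r$s
  r <- add_block(p, s, "bot_2", 8 * f, 8 * f); p <- r$p; s <- r$s
  up_in <- c(8 * f, 4 * f, 2 * f)
  for (st in 3:1) {
    cs <- chans[st]
    r <- add_block(p, s, sprintf("up%d", st), up_in[4 - st], cs)
    p <- r$p; s <- r$s
    p[[sprintf("att%d", st)]] <- new_gate(cs, cs)
    r <- add_block(p, s, sprintf("dec%d_1", st), 2 * cs, cs); p <- r$p; s <- r$s
    r <- add_block(p, s, sprintf("dec%d_2", st), cs, cs); p <- r$p; s <- r$s
  }
  p$head <- list(W = he_init(f, 2), b = numeric(2))
  new("UNetModel", spec = spec, params = p, state = s,
      history = data.frame())
}

#' Number of trainable parameters
#'
#' @param model a [UNetModel-class].
#' @return integer count of weights, biases and batch-norm parameters.
#' @export
countParams <- function(model) {
  sum(vapply(unlist(model@params, recursive = FALSE),
             length, numeric(1)))
}

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: %d stages, %d base filters, %d parameters%s\n",
              object@spec$stages, object@spec$baseFilters,
              countParams(object),
              if (nrow(object@history)) sprintf(", trained %d epochs",
                                                max(object@history$epoch))
              else " (untrained)"))
  invisible(NULL)
})

# --- primitive layers -------------------------------------------------------
# Activations are (H, W, B, C) arrays, so matrix(x, ncol = C) puts channels
# in columns with no permutation. Convolutions carry no bias: every conv is
# followed by batch normalization, whose shift absorbs it.

conv_fw <- function(x, layer) {
  d <- dim(x)
  xc <- im2col3_cpp(x, d[1], d[2], d[3], d[4])
  y <- xc %*% layer$W
  dim(y) <- c(d[1], d[2], d[3], ncol(layer$W))
  list(y = y, xc = xc, din = d)
}

conv_bw <- function(dy, cache, layer) {
  d <- dim(dy)
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  dW <- crossprod(cache$xc, dym)
  dxc <- dym %*% t(layer$W)
  dx <- col2im3_cpp(dxc, cache$din[1], cache$din[2], cache$din[3],
                    cache$din[4])
  list(dx = dx, dW = dW)
}

convt_fw <- function(x, layer) {
  d <- dim(x)
  y <- convt3_fw_cpp(x, layer$W, d[1], d[2], d[3], d[4])
  list(y = y, x = x, din = d)
}

convt_bw <- function(dy, cache, layer) {
  d <- cache$din
  dx <- convt3_bwx_cpp(dy, layer$W, d[1], d[2], d[3], d[4])
  dW <- convt3_bww_cpp(cache$x, dy, d[1], d[2], d[3], d[4],
                       ncol(layer$W))
  list(dx = dx, dW = dW)
}

# batch-norm + ReLU, fused in C++. In training mode batch statistics are
# used and the running statistics updated; at inference the running
# statistics apply.
bnrelu_fw <- function(x, layer, run, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2] * d[3]
  C <- d[4]
  if (training) {
    st <- bn_stats_cpp(x, n, C)
    mu <- st$mean
    v <- st$var
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
    run$n <- run$n + 1
  } else {
    mu <- run$mean
    v <- run$var
  }
  istd <- 1 / sqrt(v + eps)
  r <- bn_relu_fw_cpp(x, n, C, mu, istd, layer$gamma, layer$beta)
  dim(r$y) <- d
  list(y = r$y, xhat = r$xhat, istd = istd, run = run, d = d)
}

bnrelu_bw <- function(dy, cache, layer) {
  d <- cache$d
  n <- d[1] * d[2] * d[3]
  r <- bn_relu_bw_cpp(dy, cache$y, cache$xhat, n, d[4], layer$gamma,
                      cache$istd)
  dim(r$dx) <- d
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

pool_fw <- function(x) {
  d <- dim(x)
  r <- maxpool2_cpp(x, d[1], d[2], d[3], d[4])
  list(y = r$out, idx = r$idx, din = d)
}

pool_bw <- function(dy, cache) {
  dx <- array(0, cache$din)
  dx[cache$idx] <- dy
  dx
}

# attention gate: additive attention on the skip connection
gate_fw <- function(s, g, layer) {
  d <- dim(s)
  n <- d[1] * d[2] * d[3]
  sm <- s
  dim(sm) <- c(n, d[4])
  gm <- g
  dim(gm) <- c(n, dim(g)[4])
  pre <- sm %*% layer$Wx + gm %*% layer$Wg
  pre <- pre + rep(layer$bg, each = n)
  a <- pre * (pre > 0)
  psi <- drop(a %*% layer$Wp) + layer$bp
  alpha <- 1 / (1 + exp(-psi))
  y <- sm * alpha
  dim(y) <- d
  list(y = y, sm = sm, gm = gm, pre = pre, a = a, alpha = alpha, d = d,
       dg = dim(g))
}

gate_bw <- function(dy, cache, layer) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  dalpha <- rowSums(dym * cache$sm)
  dsm <- dym * cache$alpha
  dpsi <- dalpha * cache$alpha * (1 - cache$alpha)
  dWp <- crossprod(cache$a, dpsi)
  dbp <- sum(dpsi)
  da <- outer(dpsi, drop(layer$Wp))
  dpre <- da * (cache$pre > 0)
  dWx <- crossprod(cache$sm, dpre)
  dWg <- crossprod(cache$gm, dpre)
  dbg <- colSums(dpre)
  ds <- dsm + dpre %*% t(layer$Wx)
  dg <- dpre %*% t(layer$Wg)
  dim(ds) <- d
  dim(dg) <- cache$dg
  list(ds = ds, dg = dg, dWx = dWx, dWg = dWg, dbg = dbg, dWp = dWp,
       dbp = dbp)
}

# conv + BN + ReLU block; up = TRUE uses the stride-2 transposed convolution
block_fw <- function(x, params, state, name, training, up = FALSE) {
  c1 <- if (up) convt_fw(x, params[[paste0(name, "_conv")]]) else
    conv_fw(x, params[[paste0(name, "_conv")]])
  b1 <- bnrelu_fw(c1$y, params[[paste0(name, "_bn")]],
                  state[[paste0(name, "_bn")]], training)
  list(y = b1$y, conv = c1, bn = b1, run = b1$run, up = up)
}

block_bw <- function(dy, cache, params, name, grads) {
  b <- bnrelu_bw(dy, cache$bn, params[[paste0(name, "_bn")]])
  cv <- if (cache$up) convt_bw(b$dx, cache$conv,
                               params[[paste0(name, "_conv")]]) else
    conv_bw(b$dx, cache$conv, params[[paste0(name, "_conv")]])
  grads[[paste0(name, "_bn")]] <- list(gamma = b$dgamma, beta = b$dbeta)
  grads[[paste0(name, "_conv")]] <- list(W = cv$dW)
  list(dx = cv$dx, grads = grads)
}

# full network forward; returns vessel probabilities, caches for backprop and
# (in training mode) updated batch-norm running statistics
unet_fw <- function(params, state, x, training) {
  K <- list()
  run_block <- function(x, name, up = FALSE) {
    r <- block_fw(x, params, state, name, training, up = up)
    if (training) state[[paste0(name, "_bn")]] <<- r$run
    K[[name]] <<- r
    r$y
  }
  e1 <- run_block(run_block(x, "enc1_1"), "enc1_2")
  p1 <- pool_fw(e1); K$pool1 <- p1
  e2 <- run_block(run_block(p1$y, "enc2_1"), "enc2_2")
  p2 <- pool_fw(e2); K$pool2 <- p2
  e3 <- run_block(run_block(p2$y, "enc3_1"), "enc3_2")
  p3 <- pool_fw(e3); K$pool3 <- p3
  bt <- run_block(run_block(p3$y, "bot_1"), "bot_2")
  skips <- list(e1, e2, e3)
  cur <- bt
  for (st in 3:1) {
    u <- run_block(cur, sprintf("up%d", st), up = TRUE)
    gname <- sprintf("att%d", st)
    gt <- gate_fw(skips[[st]], u, params[[gname]])
    K[[gname]] <- gt
    cat_x <- cbind4(gt$y, u)
    K[[sprintf("cat%d", st)]] <- c(dim(gt$y)[4], dim(u)[4])
    cur <- run_block(run_block(cat_x, sprintf("dec%d_1", st)),
                     sprintf("dec%d_2", st))
  }
  d <- dim(cur)
  cm <- cur
  dim(cm) <- c(d[1] * d[2] * d[3], d[4])
  logits <- cm %*% params$head$W
  logits <- logits + rep(params$head$b, each = nrow(logits))
  mx <- pmax(logits[, 1], logits[, 2])
  ez <- exp(logits - mx)
  p1v <- ez[, 2] / (ez[, 1] + ez[, 2])
  K$head <- list(cm = cm, p1 = p1v, d = d)
  prob <- array(p1v, c(d[1], d[2], d[3]))
  list(prob = prob, caches = K, state = state)
}

# concatenate along the channel (4th) dimension
cbind4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# backward pass from the gradient of the loss w.r.t. the vessel probability
unet_bw <- function(params, K, dprob) {
  grads <- list()
  hd <- K$head
  p1 <- hd$p1
  dp <- as.numeric(dprob)
  dz1 <- dp * p1 * (1 - p1)
  dlog <- cbind(-dz1, dz1)
  grads$head <- list(W = crossprod(hd$cm, dlog), b = colSums(dlog))
  dcur <- dlog %*% t(params$head$W)
  dim(dcur) <- hd$d
  back_block <- function(dy, name) {
    r <- block_bw(dy, K[[name]], params, name, grads)
    grads <<- r$grads
    r$dx
  }
  dskip <- list()
  for (st in 1:3) {
    dcur <- back_block(back_block(dcur, sprintf("dec%d_2", st)),
                       sprintf("dec%d_1", st))
    nc <- K[[sprintf("cat%d", st)]]
    dgate_y <- dcur[, , , seq_len(nc[1]), drop = FALSE]
    du <- dcur[, , , nc[1] + seq_len(nc[2]), drop = FALSE]
    gname <- sprintf("att%d", st)
    gb <- gate_bw(dgate_y, K[[gname]], params[[gname]])
    grads[[gname]] <- list(Wx = gb$dWx, Wg = gb$dWg, bg = gb$dbg,
                           Wp = gb$dWp, bp = gb$dbp)
    dskip[[st]] <- gb$ds
    dcur <- back_block(du + gb$dg, sprintf("up%d", st))
  }
  dp3 <- back_block(back_block(dcur, "bot_2"), "bot_1")
  de3 <- pool_bw(dp3, K$pool3) + dskip[[3]]
  dp2 <- back_block(back_block(de3, "enc3_2"), "enc3_1")
  de2 <- pool_bw(dp2, K$pool2) + dskip[[2]]
  dp1 <- back_block(back_block(de2, "enc2_2"), "enc2_1")
  de1 <- pool_bw(dp1, K$pool1) + dskip[[1]]
  back_block(back_block(de1, "enc1_2"), "enc1_1")
  grads
}

# Dice loss over a batch and its gradient w.r.t. the vessel probability
dice_loss_grad <- function(prob, truth, smooth = 1e-6) {
  A <- 2 * sum(prob * truth) + smooth
  Bden <- sum(prob^2) + sum(truth^2) + smooth
  dice <- A / Bden
  dprob <- -(2 * truth * Bden - A * 2 * prob) / Bden^2
  list(loss = 1 - dice, dprob = dprob)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with initial
#' learning rate 5e-5, 150 epochs, a 4:1 train/validation split, Dice loss,
#' and learning-rate reduction by a factor 0.1 when the validation loss has
#' not improved for 15 epochs.
#'
#' @param epochs training epochs.
#' @param lr initial Adam learning rate.
#' @param lrFactor multiplicative learning-rate reduction on plateau.
#' @param patience epochs without validation improvement before reducing.
#' @param valFraction validation fraction (default 0.2, i.e. 4:1).
#' @param batchSize minibatch size.
#' @param seed RNG seed controlling the split and shuffling.
#' @return list of class parameters for [trainUNet()].
#' @export
trainConfig <- function(epochs = 150, lr = 5e-5, lrFactor = 0.1,
                        patience = 15, valFraction = 0.2, batchSize = 32,
                        seed = 1) {
  stopifnot(valFraction > 0, valFraction < 1, patience < epochs)
  list(epochs = as.integer(epochs), lr = lr, lrFactor = lrFactor,
       patience = as.integer(patience), valFraction = valFraction,
       batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Train/validation split sizes
#'
#' The split used by [trainUNet()]: `round(valFraction * n)` patches go to
#' validation and the rest to training (e.g. 300,000 patches at the default
#' 4:1 ratio give 240,000 / 60,000).
#'
#' @param n total patch count.
#' @param valFraction validation fraction.
#' @return named vector `c(train, val)`.
#' @export
patchSplit <- function(n, valFraction = 0.2) {
  nval <- max(1, round(valFraction * n))
  c(train = n - nval, val = nval)
}

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = c("matrix", "numeric", "array"))
}

adam_step <- function(params, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      g <- grads[[ln]][[pn]]
      st <- opt[[ln]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[ln]][[pn]] <- params[[ln]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[ln]][[pn]] <- st
    }
  }
  list(params = params, opt = opt)
}

eval_loss <- function(params, state, patches, labels, idx, batchSize) {
  tot <- 0
  nb <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batchSize))) {
    x <- array(patches[, , b], c(64, 64, length(b), 1))
    fw <- unet_fw(params, state, x, training = FALSE)
    tot <- tot + dice_loss_grad(fw$prob, labels[, , b])$loss
    nb <- nb + 1
  }
  tot / nb
}

#' Train the attention U-Net
#'
#' Minimizes the Dice loss with Adam on minibatches of normalized patches.
#' The dataset is split train/validation by `cfg$valFraction`; after each
#' epoch the validation loss is evaluated, the learning rate is multiplied
#' by `cfg$lrFactor` whenever the validation loss has not improved for
#' `cfg$patience` consecutive epochs, and the weights achieving the best
#' validation loss are the ones returned. All randomness (split, shuffling)
#' derives from `cfg$seed`.
#'
#' @param model an untrained or pre-trained [UNetModel-class].
#' @param dataset a [PatchDataset-class].
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch progress?
#' @return the trained [UNetModel-class] with a populated `history` slot
#'   (per-epoch train loss, validation loss and learning rate).
#' @export
trainUNet <- function(model, dataset, cfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), is(dataset, "PatchDataset"))
  n <- dim(dataset@patches)[3]
  if (n < 2) stopf("dataset too small to split")
  withr::local_seed(cfg$seed)
  perm <- sample(n)
  nval <- patchSplit(n, cfg$valFraction)[["val"]]
  val_idx <- perm[seq_len(nval)]
  train_idx <- perm[(nval + 1):n]
  params <- model@params
  state <- model@state
  opt <- adam_init(params)
  lr <- cfg$lr
  t <- 0
  best_val <- Inf
  best <- list(params = params, state = state)
  stall <- 0
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    tr_loss <- 0
    nb <- 0
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
      x <- array(dataset@patches[, , b], c(64, 64, length(b), 1))
      q <- dataset@labels[, , b]
      fw <- unet_fw(params, state, x, training = TRUE)
      state <- fw$state
      lg <- dice_loss_grad(fw$prob, q)
      grads <- unet_bw(params, fw$caches, lg$dprob)
      t <- t + 1
      up <- adam_step(params, grads, opt, lr, t)
      params <- up$params
      opt <- up$opt
      tr_loss <- tr_loss + lg$loss
      nb <- nb + 1
    }
    val_loss <- eval_loss(params, state, dataset@patches, dataset@labels,
                          val_idx, cfg$batchSize)
    if (val_loss < best_val - 1e-5) {
      best_val <- val_loss
      best <- list(params = params, state = state)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= cfg$patience) {
        lr <- lr * cfg$lrFactor
        stall <- 0
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss / nb,
                             val_loss = val_loss, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      ep, tr_loss / nb, val_loss, lr))
  }
  new("UNetModel", spec = model@spec, params = best$params,
      state = best$state, history = do.call(rbind, hist))
}

#' Segment a full image or frame sequence
#'
#' For a [FrameSequence-class], the first `averageN` frames are averaged to
#' suppress moving-cell texture and reveal faint vessels (if fewer frames are
#' available, all are used with a warning). The (optionally preprocessed)
#' image is tiled into 64 x 64 windows with 50% overlap, each tile is
#' normalized exactly as the training patches were, the vessel probabilities
#' are blended by averaging in the overlaps, and the result is thresholded.
#'
#' @param model a trained [UNetModel-class].
#' @param x a [FrameSequence-class] or a 2-D image matrix.
#' @param threshold vessel probability threshold (default 0.5).
#' @param averageN number of frames to average (default 30).
#' @param preprocess apply [preprocessFrame()] (green channel, 0.5x resize,
#'   CLAHE) before tiling?
#' @param scale resize factor used when `preprocess = TRUE`.
#' @return binary mask (0/1 matrix) at the (preprocessed) image size.
#' @export
predictMask <- function(model, x, threshold = 0.5, averageN = 30,
                        preprocess = TRUE, scale = 0.5) {
  stopifnot(is(model, "UNetModel"))
  img <- if (is(x, "FrameSequence")) {
    n <- min(averageN, nFrames(x))
    if (n < averageN)
      warning(sprintf("only %d frames available; averaging all of them", n))
    apply(x@frames[, , seq_len(n), drop = FALSE], c(1, 2), mean)
  } else {
    x
  }
  if (preprocess) img <- preprocessFrame(img, scale = scale)
  h <- nrow(img)
  w <- ncol(img)
  ph <- max(64, 32 * ceiling(h / 32))
  pw <- max(64, 32 * ceiling(w / 32))
  pad <- matrix(stats::median(img), ph, pw)
  pad[seq_len(h), seq_len(w)] <- img
  rows <- unique(c(seq(1, ph - 63, 32)))
  cols <- unique(c(seq(1, pw - 63, 32)))
  acc <- matrix(0, ph, pw)
  cnt <- matrix(0, ph, pw)
  tiles <- expand.grid(r = rows, c = cols)
  bs <- 32
  for (start in seq(1, nrow(tiles), bs)) {
    sel <- start:min(nrow(tiles), start + bs - 1)
    xb <- array(0, c(64, 64, length(sel), 1))
    for (k in seq_along(sel)) {
      r0 <- tiles$r[sel[k]]
      c0 <- tiles$c[sel[k]]
      xb[, , k, 1] <- normalize_patch(pad[r0:(r0 + 63), c0:(c0 + 63)])
    }
    fw <- unet_fw(model@params, model@state, xb, training = FALSE)
    for (k in seq_along(sel)) {
      r0 <- tiles$r[sel[k]]
      c0 <- tiles$c[sel[k]]
      acc[r0:(r0 + 63), c0:(c0 + 63)] <-
        acc[r0:(r0 + 63), c0:(c0 + 63)] + fw$prob[, , k]
      cnt[r0:(r0 + 63), c0:(c0 + 63)] <-
        cnt[r0:(r0 + 63), c0:(c0 + 63)] + 1
    }
  }
  prob <- acc / cnt
  ((prob > threshold) * 1L)[seq_len(h), seq_len(w)]
}
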