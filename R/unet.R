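#' @include AllClasses.R segmentation.R
NULL

# ---- minimal deterministic conv-net machinery (arrays H x W x C) -------
# The trainable backend is a compact two-level encoder-decoder with skip
# connections, written directly on BLAS matrix products (im2col): small
# enough to train on synthetic frames in seconds, fully deterministic
# given a seed, and exposing the same contract as the classical backend.

.pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

# (H*W) x (9*C) patch matrix, offset-major column order
.im2col <- function(x) {
  d <- dim(x)
  p <- .pad1(x)
  cols <- vector("list", 9L)
  o <- 1L
  for (dj in 0:2) for (di in 0:2) {
    blk <- p[di + seq_len(d[1]), dj + seq_len(d[2]), , drop = FALSE]
    cols[[o]] <- matrix(blk, nrow = d[1] * d[2])
    o <- o + 1L
  }
  do.call(cbind, cols)
}

.col2im <- function(dcols, d) {
  p <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  o <- 1L
  for (dj in 0:2) for (di in 0:2) {
    idx <- ((o - 1L) * d[3] + 1L):(o * d[3])
    blk <- array(dcols[, idx], dim = d)
    p[di + seq_len(d[1]), dj + seq_len(d[2]), ] <-
      p[di + seq_len(d[1]), dj + seq_len(d[2]), , drop = FALSE] + blk
    o <- o + 1L
  }
  p[2:(d[1] + 1L), 2:(d[2] + 1L), , drop = FALSE]
}

.convFwd <- function(x, W, b) {
  d <- dim(x)
  X <- .im2col(x)
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = array(Y, dim = c(d[1], d[2], ncol(W))), X = X, inDim = d)
}

.convBwd <- function(cache, dOut, W) {
  dY <- matrix(dOut, nrow = nrow(cache$X))
  list(dW = crossprod(cache$X, dY),
       db = colSums(dY),
       dX = .col2im(dY %*% t(W), cache$inDim))
}

.relu <- function(x) { x[x < 0] <- 0; x }
.reluBwd <- function(dOut, act) { dOut[act <= 0] <- 0; dOut }

.pool2 <- function(x) {
  d <- dim(x)
  r <- seq(1L, d[1], 2L); c2 <- seq(1L, d[2], 2L)
  (x[r, c2, , drop = FALSE] + x[r + 1L, c2, , drop = FALSE] +
     x[r, c2 + 1L, , drop = FALSE] + x[r + 1L, c2 + 1L, , drop = FALSE]) / 4
}

.pool2Bwd <- function(dOut, inDim) {
  up <- dOut[rep(seq_len(dim(dOut)[1]), each = 2L),
             rep(seq_len(dim(dOut)[2]), each = 2L), , drop = FALSE] / 4
  array(up, dim = inDim)
}

.up2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2L),
    rep(seq_len(dim(x)[2]), each = 2L), , drop = FALSE]
}

.up2Bwd <- function(dOut) .pool2(dOut) * 4

.concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

.heInit <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

.unetInit <- function(C, nClasses) {
  list(
    W1 = .heInit(9L, C),           b1 = numeric(C),
    W2 = .heInit(9L * C, C),       b2 = numeric(C),
    W3 = .heInit(9L * C, 2L * C),  b3 = numeric(2L * C),
    W4 = .heInit(18L * C, 2L * C), b4 = numeric(2L * C),
    W5 = .heInit(18L * C, 4L * C), b5 = numeric(4L * C),
    W6 = .heInit(54L * C, 2L * C), b6 = numeric(2L * C),
    W7 = .heInit(27L * C, C),      b7 = numeric(C),
    W8 = .heInit(C, nClasses),     b8 = numeric(nClasses)
  )
}

.unetForward <- function(x, P) {
  if (is.null(dim(x)) || length(dim(x)) == 2L)
    x <- array(x, dim = c(dim(x), 1L))
  c1 <- .convFwd(x, P$W1, P$b1);  a1 <- .relu(c1$out)
  c2 <- .convFwd(a1, P$W2, P$b2); a2 <- .relu(c2$out)        # skip e1
  p1 <- .pool2(a2)
  c3 <- .convFwd(p1, P$W3, P$b3); a3 <- .relu(c3$out)
  c4 <- .convFwd(a3, P$W4, P$b4); a4 <- .relu(c4$out)        # skip e2
  p2 <- .pool2(a4)
  c5 <- .convFwd(p2, P$W5, P$b5); a5 <- .relu(c5$out)
  u1 <- .up2(a5); k1 <- .concatC(u1, a4)
  c6 <- .convFwd(k1, P$W6, P$b6); a6 <- .relu(c6$out)
  u2 <- .up2(a6); k2 <- .concatC(u2, a2)
  c7 <- .convFwd(k2, P$W7, P$b7); a7 <- .relu(c7$out)
  d <- dim(a7)
  logits <- sweep(matrix(a7, ncol = d[3]) %*% P$W8, 2L, P$b8, "+")
  list(logits = array(logits, dim = c(d[1], d[2], ncol(P$W8))),
       cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, p1 = p1,
                    c3 = c3, a3 = a3, c4 = c4, a4 = a4, p2 = p2,
                    c5 = c5, a5 = a5, u1 = u1, c6 = c6, a6 = a6,
                    u2 = u2, c7 = c7, a7 = a7))
}

.unetBackward <- function(dLogits, fw, P) {
  ca <- fw$cache
  g <- list()
  d7 <- dim(ca$a7)
  dMat <- matrix(dLogits, ncol = dim(dLogits)[3])
  A7 <- matrix(ca$a7, ncol = d7[3])
  g$W8 <- crossprod(A7, dMat); g$b8 <- colSums(dMat)
  dA7 <- array(dMat %*% t(P$W8), dim = d7)
  dA7 <- .reluBwd(dA7, ca$a7)
  b7 <- .convBwd(ca$c7, dA7, P$W7); g$W7 <- b7$dW; g$b7 <- b7$db
  nU2 <- dim(ca$u2)[3]
  dU2 <- b7$dX[, , seq_len(nU2), drop = FALSE]
  dA2skip <- b7$dX[, , nU2 + seq_len(dim(ca$a2)[3]), drop = FALSE]
  dA6 <- .reluBwd(.up2Bwd(dU2), ca$a6)
  b6 <- .convBwd(ca$c6, dA6, P$W6); g$W6 <- b6$dW; g$b6 <- b6$db
  nU1 <- dim(ca$u1)[3]
  dU1 <- b6$dX[, , seq_len(nU1), drop = FALSE]
  dA4skip <- b6$dX[, , nU1 + seq_len(dim(ca$a4)[3]), drop = FALSE]
  dA5 <- .reluBwd(.up2Bwd(dU1), ca$a5)
  b5 <- .convBwd(ca$c5, dA5, P$W5); g$W5 <- b5$dW; g$b5 <- b5$db
  dP2 <- b5$dX
  dA4 <- .reluBwd(.pool2Bwd(dP2, dim(ca$a4)) + dA4skip, ca$a4)
  b4 <- .convBwd(ca$c4, dA4, P$W4); g$W4 <- b4$dW; g$b4 <- b4$db
  dA3 <- .reluBwd(b4$dX, ca$a3)
  b3 <- .convBwd(ca$c3, dA3, P$W3); g$W3 <- b3$dW; g$b3 <- b3$db
  dP1 <- b3$dX
  dA2 <- .reluBwd(.pool2Bwd(dP1, dim(ca$a2)) + dA2skip, ca$a2)
  b2 <- .convBwd(ca$c2, dA2, P$W2); g$W2 <- b2$dW; g$b2 <- b2$db
  dA1 <- .reluBwd(b2$dX, ca$a1)
  b1 <- .convBwd(ca$c1, dA1, P$W1); g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

# cross-entropy + soft-DICE loss; returns loss value and dLogits
.segLoss <- function(logits, labels, nClasses = 4L) {
  d <- dim(logits)
  n <- d[1] * d[2]
  L <- matrix(logits, ncol = d[3])
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  Pm <- E / rowSums(E)
  oneHot <- matrix(0, n, nClasses)
  oneHot[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  ce <- -mean(log(pmax(rowSums(Pm * oneHot), 1e-12)))
  dP_ce <- -oneHot / pmax(Pm, 1e-12) / n
  eps <- 1e-6
  inter <- colSums(Pm * oneHot)
  sums <- colSums(Pm) + colSums(oneHot) + eps
  diceC <- 2 * inter / sums
  diceLoss <- 1 - mean(diceC)
  dP_dice <- -(sweep(oneHot, 2L, 2 * sums, "*") -
                 matrix(2 * inter, n, nClasses, byrow = TRUE)) /
    matrix(sums^2, n, nClasses, byrow = TRUE) / nClasses
  dP <- dP_ce + dP_dice
  dL <- Pm * (dP - rowSums(dP * Pm))
  list(loss = ce + diceLoss, ce = ce, dice = diceLoss,
       dLogits = array(dL, dim = d))
}

.adamStep <- function(P, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(P)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    P[[nm]] <- P[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(P = P, state = state)
}

#' Segmentation model configuration
#'
#' @param inputSize working resolution `c(rows, cols)`; both must be
#'   divisible by 4. 256 x 256 is the clinical input convention; the
#'   synthetic training runs in this package default to 64 x 64.
#' @param nClasses number of output classes (4).
#' @param epochs,learningRate,batchSize,baseChannels training
#'   hyperparameters for the trainable backend.
#' @param seed RNG seed controlling initialization and batch order.
#' @return list of class `"segModelConfig"`.
#' @export
segModelConfig <- function(inputSize = c(64L, 64L), nClasses = 4L,
                           epochs = 5L, learningRate = 1e-2,
                           batchSize = 2L, baseChannels = 8L, seed = 0L) {
  inputSize <- as.integer(inputSize)
  if (any(inputSize %% 4L != 0L))
    stop("'inputSize' dimensions must be divisible by 4")
  structure(list(inputSize = inputSize, nClasses = as.integer(nClasses),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 baseChannels = as.integer(baseChannels),
                 seed = as.integer(seed)),
            class = "segModelConfig")
}

#' Train the encoder-decoder segmentation backend
#'
#' Trains a compact two-level U-style encoder-decoder (3x3 convolutions,
#' 2x2 mean-pool downsampling, nearest-neighbour upsampling with skip
#' concatenation, 4-channel output) with per-pixel cross-entropy plus
#' soft-DICE loss and Adam. Frames and masks are resized to the working
#' resolution (bilinear / nearest-neighbour respectively). Training is
#' deterministic given `config$seed` under single-threaded execution.
#'
#' @param framesList list of 2D grayscale frames (any shape).
#' @param masksList list of integer label masks co-registered with the
#'   frames.
#' @param config a [segModelConfig()].
#' @param split optional list with `train` and `val` index vectors; by
#'   default a 6:2:2 split ([splitDataset()]) with the config seed.
#' @return object of class `"unetModel"`: trained weights, the config,
#'   per-epoch losses, and per-class validation DICE (`valDice`).
#' @export
trainUnet <- function(framesList, masksList, config = segModelConfig(),
                      split = NULL) {
  n <- length(framesList)
  if (n == 0L) stop("data error: empty training set")
  if (length(masksList) != n) stop("frames and masks must pair one-to-one")
  if (is.null(split)) split <- splitDataset(n, seed = config$seed)
  if (length(split$train) == 0L) stop("data error: empty training set")
  sz <- config$inputSize
  X <- lapply(framesList, preprocessFrame, size = sz)
  Y <- lapply(masksList, function(m) nearestResize(m, sz))
  P <- .withSeed(config$seed, .unetInit(config$baseChannels, config$nClasses))
  state <- list(m = lapply(P, function(w) w * 0),
                v = lapply(P, function(w) w * 0))
  t <- 0L
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- .withSeed(config$seed + ep, sample(split$train))
    epLoss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batchSize - 1L, length(ord))]
      g <- NULL
      bLoss <- 0
      for (ii in idx) {
        fw <- .unetForward(X[[ii]], P)
        ls <- .segLoss(fw$logits, Y[[ii]], config$nClasses)
        gi <- .unetBackward(ls$dLogits, fw, P)
        g <- if (is.null(g)) gi else Map(`+`, g, gi)
        bLoss <- bLoss + ls$loss
      }
      g <- lapply(g, function(x) x / length(idx))
      t <- t + 1L
      upd <- .adamStep(P, g, state, config$learningRate, t)
      P <- upd$P; state <- upd$state
      epLoss <- epLoss + bLoss / length(idx)
      nb <- nb + 1L
      i <- i + config$batchSize
    }
    history[ep] <- epLoss / max(nb, 1L)
  }
  model <- structure(list(weights = P, config = config, history = history),
                     class = "unetModel")
  model$valDice <- if (length(split$val) > 0L)
    .validationDice(model, X[split$val], Y[split$val]) else NULL
  model$split <- split
  model
}

# pooled per-class DICE over a set of frames
.validationDice <- function(model, X, Y) {
  nC <- model$config$nClasses
  inter <- numeric(nC); szSum <- numeric(nC)
  for (i in seq_along(X)) {
    pred <- predictUnet(model, X[[i]])
    for (cls in seq_len(nC) - 1L) {
      p <- pred == cls; t <- Y[[i]] == cls
      inter[cls + 1L] <- inter[cls + 1L] + sum(p & t)
      szSum[cls + 1L] <- szSum[cls + 1L] + sum(p) + sum(t)
    }
  }
  dice <- ifelse(szSum > 0, 2 * inter / szSum, 1)
  names(dice) <- names(.CLS)[seq_len(nC)]
  c(dice, mean = mean(dice))
}

#' Predict a label mask with a trained model
#'
#' @param model a `"unetModel"` from [trainUnet()].
#' @param frame 2D frame already at the model's working resolution (use
#'   [preprocessFrame()] first if needed).
#' @return integer matrix of class codes.
#' @export
predictUnet <- function(model, frame) {
  stopifnot(inherits(model, "unetModel"))
  if (!identical(dim(frame), as.integer(model$config$inputSize)))
    frame <- preprocessFrame(frame, model$config$inputSize)
  fw <- .unetForward(frame, model$weights)
  d <- dim(fw$logits)
  cls <- max.col(matrix(fw$logits, ncol = d[3]), ties.method = "first") - 1L
  matrix(as.integer(cls), d[1], d[2])
}

#' Save / load a trained model
#'
#' The model (weights, config, seed, history) is serialized with
#' `saveRDS`; a runtime artefact, not a distribution format.
#'
#' @param model a `"unetModel"`.
#' @param path destination `.rds` path.
#' @return `path` invisibly (write) or the model (read).
#' @export
writeUnetModel <- function(model, path) {
  stopifnot(inherits(model, "unetModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeUnetModel
#' @export
readUnetModel <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unetModel")) stop("not a serialized unet model")
  model
}
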