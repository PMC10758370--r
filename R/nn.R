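# Self-contained CNN engine.
#
# Forward/backward passes for the backbone's layer vocabulary (conv3x3
# stride 1 / padding 1, batch normalization, ReLU, 2x2 stride-2 max
# pooling, global average pooling, fully connected, softmax cross-entropy)
# on dense R arrays, with convolutions lowered to BLAS matrix products via
# im2col.  Activations are arrays of dimension (H, W, C, N).  Everything
# is double precision and deterministic under a seed; the engine targets
# desk-scale inputs (small images, narrow networks).

bnEps <- 1e-5

# ---- im2col convolution --------------------------------------------------

padActivations <- function(x, p = 1L) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# (H*W*N) x (9*C) patch matrix; rows ordered h fastest, then w, then n;
# columns grouped by tap (dy, dx) with dy fastest, each tap spanning C
im2col <- function(xp, H, W) {
  C <- dim(xp)[3]; N <- dim(xp)[4]
  X <- matrix(0, H * W * N, 9L * C)
  tap <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    tap <- tap + 1L
    s <- xp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE]
    X[, (tap - 1L) * C + seq_len(C)] <-
      matrix(aperm(s, c(1, 2, 4, 3)), H * W * N, C)
  }
  X
}

convForward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[4]
  X <- im2col(padActivations(x), H, Wd)
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  out <- aperm(array(Y, c(H, Wd, N, ncol(W))), c(1, 2, 4, 3))
  list(out = out, X = X)
}

convBackward <- function(dOut, X, W, inDim) {
  H <- dim(dOut)[1]; Wd <- dim(dOut)[2]; N <- dim(dOut)[4]
  dY <- matrix(aperm(dOut, c(1, 2, 4, 3)), H * Wd * N, dim(dOut)[3])
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  C <- inDim[3]
  dxp <- array(0, c(inDim[1] + 2L, inDim[2] + 2L, C, inDim[4]))
  tap <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    tap <- tap + 1L
    chunk <- array(dXcol[, (tap - 1L) * C + seq_len(C)], c(H, Wd, N, C))
    dxp[dy + seq_len(H), dx + seq_len(Wd), , ] <-
      dxp[dy + seq_len(H), dx + seq_len(Wd), , , drop = FALSE] +
      aperm(chunk, c(1, 2, 4, 3))
  }
  dx <- dxp[1L + seq_len(inDim[1]), 1L + seq_len(inDim[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization -------------------------------------------------

bnForward <- function(x, gamma, beta, runMean, runVar, training,
                      momentum = 0.9) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    runMean <- momentum * runMean + (1 - momentum) * mu
    runVar <- momentum * runVar + (1 - momentum) * v
  } else {
    mu <- runMean; v <- runVar
  }
  invStd <- 1 / sqrt(v + bnEps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invStd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- aperm(array(y, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = out, xhat = xhat, invStd = invStd,
       runMean = runMean, runVar = runVar)
}

bnBackward <- function(dOut, cache, gamma, training) {
  d <- dim(dOut); C <- d[3]
  dy <- matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (training) {
    n <- nrow(dy)
    dxhat <- sweep(dy, 2, gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dxm <- sweep(t1 - t2, 2, cache$invStd, "*")
  } else {
    dxm <- sweep(dy, 2, gamma * cache$invStd, "*")
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling / heads -----------------------------------------------------

maxpoolForward <- function(x) {
  d <- dim(x)
  r <- array(x, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  s11 <- r[1, , 1, , , , drop = FALSE]; dim(s11) <- dim(s11)[-c(1, 3)]
  s21 <- r[2, , 1, , , , drop = FALSE]; dim(s21) <- dim(s21)[-c(1, 3)]
  s12 <- r[1, , 2, , , , drop = FALSE]; dim(s12) <- dim(s12)[-c(1, 3)]
  s22 <- r[2, , 2, , , , drop = FALSE]; dim(s22) <- dim(s22)[-c(1, 3)]
  out <- pmax(s11, s21, s12, s22)
  # route gradient to the first maximal position (fixed tie-break order)
  m11 <- s11 == out
  m21 <- (s21 == out) & !m11
  m12 <- (s12 == out) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(out = out, masks = list(m11, m21, m12, m22), inDim = d)
}

maxpoolBackward <- function(dOut, cache) {
  d <- cache$inDim
  dr <- array(0, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  dr[1, , 1, , , ] <- dOut * cache$masks[[1]]
  dr[2, , 1, , , ] <- dOut * cache$masks[[2]]
  dr[1, , 2, , , ] <- dOut * cache$masks[[3]]
  dr[2, , 2, , , ] <- dOut * cache$masks[[4]]
  array(dr, d)
}

gapForward <- function(x) {
  d <- dim(x)
  feat <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(out = feat, inDim = d)
}

gapBackward <- function(dFeat, inDim) {
  scale <- 1 / (inDim[1] * inDim[2])
  array(rep(as.vector(dFeat), each = inDim[1] * inDim[2]) * scale, inDim)
}

softmaxProbs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- network construction ------------------------------------------------

#' Initialise network weights for an architecture
#'
#' He-normal initialisation for convolutional and fully-connected weights,
#' unit scale / zero shift for batch normalization.  Deterministic under
#' the seed.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed integer seed.
#' @return a network object (list with `spec` and per-layer `params`),
#'   consumed by [trainModel()], [predictModel()] and the saliency
#'   functions.
#' @export
initNetwork <- function(spec, seed = 1L) {
  stopifnot(methods::is(spec, "ArchitectureSpec"))
  withSeed(seed, {
    params <- lapply(spec@layers, function(ly) {
      switch(ly$kind,
        conv3x3 = {
          fanIn <- 9 * ly$inChannels
          list(W = matrix(stats::rnorm(fanIn * ly$kernels,
                                       sd = sqrt(2 / fanIn)),
                          fanIn, ly$kernels),
               b = numeric(ly$kernels))
        },
        batchnorm = list(gamma = rep(1, ly$channels),
                         beta = numeric(ly$channels),
                         runMean = numeric(ly$channels),
                         runVar = rep(1, ly$channels)),
        fc = list(W = matrix(stats::rnorm(ly$inFeatures * ly$outFeatures,
                                          sd = sqrt(2 / ly$inFeatures)),
                             ly$inFeatures, ly$outFeatures),
                  b = numeric(ly$outFeatures)),
        NULL)
    })
    structure(list(spec = spec, params = params, seed = as.integer(seed)),
              class = "echonetModel")
  })
}

#' @export
print.echonetModel <- function(x, ...) {
  cat(sprintf("echonet CNN model: B=%d, base kernels %d, input %dx%d, %s parameters\n",
              x$spec@B, x$spec@baseKernels, x$spec@inputSize, x$spec@inputSize,
              format(x$spec@nParameters, big.mark = ",")))
  invisible(x)
}

# stack a list of equally sized grayscale matrices into (H, W, 1, N)
imagesToArray <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  stopifnot(is.list(images), length(images) >= 1L)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
  x
}

# labels -> class index (1 = benign, 2 = malignant)
labelsToIndex <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  idx <- match(labels, c("benign", "malignant"))
  if (anyNA(idx)) stop("labels must be 'benign' or 'malignant'")
  idx
}

# ---- forward / backward over the whole stack -----------------------------

# returns list(logits, caches); caches[[i]] holds what layer i's backward
# needs plus its output activation (`out`)
forwardPass <- function(net, x, training = FALSE) {
  layers <- net$spec@layers
  caches <- vector("list", length(layers))
  act <- x
  feat <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    p <- net$params[[i]]
    if (ly$kind == "conv3x3") {
      cf <- convForward(act, p$W, p$b)
      caches[[i]] <- list(X = cf$X, inDim = dim(act), out = cf$out)
      act <- cf$out
    } else if (ly$kind == "batchnorm") {
      bf <- bnForward(act, p$gamma, p$beta, p$runMean, p$runVar, training)
      caches[[i]] <- list(xhat = bf$xhat, invStd = bf$invStd, out = bf$out,
                          runMean = bf$runMean, runVar = bf$runVar)
      act <- bf$out
    } else if (ly$kind == "relu") {
      mask <- act > 0
      act <- act * mask
      caches[[i]] <- list(mask = mask, out = act)
    } else if (ly$kind == "maxpool2x2") {
      mp <- maxpoolForward(act)
      caches[[i]] <- mp
      act <- mp$out
    } else if (ly$kind == "gap") {
      gp <- gapForward(act)
      caches[[i]] <- gp
      feat <- gp$out
    } else if (ly$kind == "fc") {
      G <- t(feat)                       # N x C
      logits <- sweep(G %*% p$W, 2, p$b, "+")
      caches[[i]] <- list(G = G, out = logits)
      feat <- logits
    } else if (ly$kind == "softmax") {
      probs <- softmaxProbs(feat)
      caches[[i]] <- list(out = probs)
    }
  }
  list(logits = caches[[length(layers) - 1L]]$out,
       probs = caches[[length(layers)]]$out,
       caches = caches)
}

# backpropagate dLogits (N x 2).  Returns parameter gradients and, when
# `stopAtLayer` is set, the gradient with respect to that layer's output
# activations (backprop then stops there).
backwardPass <- function(net, caches, dLogits, training = FALSE,
                         stopAtLayer = NULL) {
  layers <- net$spec@layers
  grads <- vector("list", length(layers))
  # walk backwards, skipping the softmax layer (dLogits already includes it)
  d <- dLogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (!is.null(stopAtLayer) && i == stopAtLayer)
      return(list(grads = grads, dAct = d))
    p <- net$params[[i]]
    cache <- caches[[i]]
    if (ly$kind == "softmax") {
      next
    } else if (ly$kind == "fc") {
      grads[[i]] <- list(dW = crossprod(cache$G, d), db = colSums(d))
      d <- t(d %*% t(p$W))               # back to C x N feature gradient
    } else if (ly$kind == "gap") {
      d <- gapBackward(d, cache$inDim)
    } else if (ly$kind == "maxpool2x2") {
      d <- maxpoolBackward(d, cache)
    } else if (ly$kind == "relu") {
      d <- d * cache$mask
    } else if (ly$kind == "batchnorm") {
      bb <- bnBackward(d, cache, p$gamma, training)
      grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      d <- bb$dx
    } else if (ly$kind == "conv3x3") {
      cb <- convBackward(d, cache$X, p$W, cache$inDim)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  list(grads = grads, dAct = d)
}

# ---- optimizers ----------------------------------------------------------

makeOptimizer <- function(kind, learnRate, momentum = 0.9) {
  state <- new.env(parent = emptyenv())
  state$t <- 0
  step <- switch(kind,
    sgdm = function(key, w, g) {
      v <- if (is.null(state[[key]])) 0 else state[[key]]
      v <- momentum * v - learnRate * g
      state[[key]] <- v
      w + v
    },
    adam = function(key, w, g) {
      mk <- paste0(key, ".m"); vk <- paste0(key, ".v")
      m <- if (is.null(state[[mk]])) 0 else state[[mk]]
      v <- if (is.null(state[[vk]])) 0 else state[[vk]]
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      state[[mk]] <- m; state[[vk]] <- v
      mhat <- m / (1 - 0.9^state$t)
      vhat <- v / (1 - 0.999^state$t)
      w - learnRate * mhat / (sqrt(vhat) + 1e-8)
    },
    rmsprop = function(key, w, g) {
      v <- if (is.null(state[[key]])) 0 else state[[key]]
      v <- 0.9 * v + 0.1 * g^2
      state[[key]] <- v
      w - learnRate * g / (sqrt(v) + 1e-8)
    },
    stop("unknown optimizer kind: ", kind))
  list(state = state, step = step)
}

classificationErrorFromProbs <- function(probs, yIdx) {
  pred <- max.col(probs, ties.method = "first")
  mean(pred != yIdx)
}

# ---- training ------------------------------------------------------------

#' Train a backbone model
#'
#' Mini-batch training of an initialised backbone with the solver, L2
#' coefficient, batch size and epoch budget taken from `hp`.  The learning
#' rate is fixed at its conventional initial value (1e-4) and SGD momentum
#' at 0.9.  L2 regularization applies to convolution and fully-connected
#' weights.  All randomness (weight init, batch shuffling) derives from
#' `seed`, so runs are exactly reproducible.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param hp a [HyperParams-class] supplying `Opt`, `Lr`, `Mn`, `Epo`.
#' @param trainImages,trainLabels training images (list of matrices sized
#'   `inputSize x inputSize`) and labels (`"benign"`/`"malignant"`).
#' @param valImages,valLabels optional validation set.
#' @param seed integer seed.
#' @param learnRate learning rate (default 1e-4).
#' @param maxEpochs optional cap overriding `hp@Epo` (e.g. for smoke runs).
#' @return an `echonetModel` with trained parameters and a `history`
#'   data.frame (per-epoch loss, train error, validation error), plus
#'   `finalTrainError` / `finalValError`.
#' @export
trainModel <- function(spec, hp, trainImages, trainLabels,
                       valImages = NULL, valLabels = NULL,
                       seed = 1L, learnRate = 1e-4, maxEpochs = NULL) {
  stopifnot(length(trainImages) >= 1L,
            length(trainImages) == length(trainLabels))
  net <- initNetwork(spec, seed = seed)
  x <- imagesToArray(trainImages)
  yIdx <- labelsToIndex(trainLabels)
  nTrain <- dim(x)[4]
  haveVal <- !is.null(valImages) && length(valImages) > 0L
  if (haveVal) {
    xv <- imagesToArray(valImages)
    yvIdx <- labelsToIndex(valLabels)
  }
  epochs <- if (is.null(maxEpochs)) hp@Epo else as.integer(maxEpochs)
  batch <- min(hp@Mn, nTrain)
  opt <- makeOptimizer(hp@Opt, learnRate)
  lambda <- hp@Lr
  layers <- spec@layers
  history <- data.frame(epoch = integer(), loss = numeric(),
                        trainError = numeric(), valError = numeric())

  withSeed(deriveSeed(seed, 7919L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nTrain)
      epLoss <- 0; epWrong <- 0
      for (start in seq(1L, nTrain, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, nTrain)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- yIdx[idx]
        fw <- forwardPass(net, xb, training = TRUE)
        probs <- fw$probs
        nb <- length(yb)
        pTrue <- probs[cbind(seq_len(nb), yb)]
        loss <- -mean(log(pmax(pTrue, 1e-12)))
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (seed %d)", ep, seed))
        epLoss <- epLoss + loss * nb
        epWrong <- epWrong + sum(max.col(probs, ties.method = "first") != yb)
        dLogits <- probs
        dLogits[cbind(seq_len(nb), yb)] <- dLogits[cbind(seq_len(nb), yb)] - 1
        dLogits <- dLogits / nb
        bw <- backwardPass(net, fw$caches, dLogits, training = TRUE)
        opt$state$t <- opt$state$t + 1
        for (i in seq_along(layers)) {
          g <- bw$grads[[i]]
          if (is.null(g)) {
            # batchnorm running stats update comes from the forward cache
            if (layers[[i]]$kind == "batchnorm") {
              net$params[[i]]$runMean <- fw$caches[[i]]$runMean
              net$params[[i]]$runVar <- fw$caches[[i]]$runVar
            }
            next
          }
          kind <- layers[[i]]$kind
          if (kind %in% c("conv3x3", "fc")) {
            net$params[[i]]$W <- opt$step(sprintf("W%d", i), net$params[[i]]$W,
                                          g$dW + lambda * net$params[[i]]$W)
            net$params[[i]]$b <- opt$step(sprintf("b%d", i),
                                          net$params[[i]]$b, g$db)
          } else if (kind == "batchnorm") {
            net$params[[i]]$runMean <- fw$caches[[i]]$runMean
            net$params[[i]]$runVar <- fw$caches[[i]]$runVar
            net$params[[i]]$gamma <- opt$step(sprintf("g%d", i),
                                              net$params[[i]]$gamma, g$dgamma)
            net$params[[i]]$beta <- opt$step(sprintf("be%d", i),
                                             net$params[[i]]$beta, g$dbeta)
          }
        }
      }
      trainErr <- epWrong / nTrain
      valErr <- if (haveVal) {
        classificationErrorFromProbs(forwardPass(net, xv)$probs, yvIdx)
      } else NA_real_
      history <- rbind(history,
                       data.frame(epoch = ep, loss = epLoss / nTrain,
                                  trainError = trainErr, valError = valErr))
      if (trainErr == 0 && ep >= 5L && !haveVal) break
    }
  })
  net$hp <- hp
  net$history <- history
  net$finalTrainError <- history$trainError[nrow(history)]
  net$finalValError <- history$valError[nrow(history)]
  net
}

#' Predict classes for new images
#'
#' Inference-mode forward pass (batch statistics frozen at their running
#' values).
#'
#' @param model a trained `echonetModel`.
#' @param images list of grayscale matrices (or an `(H, W, 1, N)` array).
#' @return list with `class` (`"benign"`/`"malignant"`), `probs`
#'   (`N x 2`, columns benign/malignant).
#' @export
predictModel <- function(model, images) {
  x <- imagesToArray(images)
  probs <- forwardPass(model, x, training = FALSE)$probs
  colnames(probs) <- c("benign", "malignant")
  list(class = c("benign", "malignant")[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' Classification error of a model on a labelled set
#'
#' @param model a trained `echonetModel`.
#' @param images images as in [predictModel()].
#' @param labels reference labels.
#' @return error rate in `[0, 1]`.
#' @export
classificationError <- function(model, images, labels) {
  pred <- predictModel(model, images)$class
  mean(pred != labels)
}
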