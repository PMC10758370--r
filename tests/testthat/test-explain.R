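# Saliency maps and the zero-entropy audit.

test_that("feature entropy matches closed-form histogram cases", {
  expect_identical(featureEntropy(matrix(0.7, 5, 5)), 0)
  two <- matrix(rep(c(0.2, 0.8), 8), 4, 4)
  expect_equal(featureEntropy(two), 1)
  m256 <- matrix(0:255 / 255, 16, 16)
  expect_equal(featureEntropy(m256), 8)
  # skewed two-value map: -p log2 p - q log2 q
  skew <- matrix(c(rep(0, 12), rep(1, 4)), 4, 4)
  expect_equal(featureEntropy(skew),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("class-logit gradients at a conv layer match finite differences", {
  net <- tinyUntrainedNet(seed = 13)
  img <- randomImage(8, seed = 40)
  sg <- saliencyGradients(net, img, 2, "conv_3")
  i <- which(layerNames(net$spec) == "conv_3")
  fw <- echonet:::forwardPass(net, echonet:::imagesToArray(list(img)))
  acts <- fw$caches[[i]]$out
  eps <- 1e-5
  set.seed(50)
  for (t in 1:25) {
    h <- sample(dim(acts)[1], 1); w <- sample(dim(acts)[2], 1)
    c <- sample(dim(acts)[3], 1)
    ap <- acts; ap[h, w, c, 1] <- ap[h, w, c, 1] + eps
    am <- acts; am[h, w, c, 1] <- am[h, w, c, 1] - eps
    fd <- (echonet:::forwardTail(net, i, ap)[1, 2] -
           echonet:::forwardTail(net, i, am)[1, 2]) / (2 * eps)
    expect_lt(abs(fd - sg$gradients[h, w, c, 1]), 1e-4)
  }
})

test_that("grad-cam equals the hand-computed rectified weighted sum", {
  net <- tinyUntrainedNet(seed = 22)
  img <- randomImage(8, seed = 41)
  sg <- saliencyGradients(net, img, 1, "conv_2")
  w <- apply(sg$gradients, 3, mean)
  cam <- matrix(0, dim(sg$activations)[1], dim(sg$activations)[2])
  for (k in seq_along(w)) cam <- cam + w[k] * sg$activations[, , k, 1]
  cam <- pmax(cam, 0)
  sal <- gradCAM(net, img, 1, "conv_2")
  grid <- saliencyGrid(sal)
  expect_equal(dim(grid), dim(img))
  expect_true(all(grid >= 0 & grid <= 1))
  if (max(cam) > 0) {
    expect_equal(max(grid), 1)
    # at matching resolution the normalized maps agree
    coarse <- echonet:::bilinearOperator(nrow(cam), nrow(cam)) %*% cam %*%
      t(echonet:::bilinearOperator(ncol(cam), ncol(cam)))
    expect_equal(grid[1, 1] > 0, coarse[1, 1] > 0)
  }
})

test_that("a frozen constant head yields an identically zero map", {
  net <- tinyUntrainedNet(seed = 30)
  fcIdx <- which(layerNames(net$spec) == "fc")
  net$params[[fcIdx]]$W[] <- 0
  sal <- gradCAM(net, randomImage(8, seed = 1), 2, "conv_3")
  expect_true(all(saliencyGrid(sal) == 0))
})

test_that("egrad-cam equals grad-cam when no map is entropy-excluded", {
  m <- tinyTrainedModel()
  img <- tinyDataset()$rois[[3]]
  audit <- zeroEntropyRatio(m, img, "conv_3")
  if (zeroEntropyPercent(audit) == 0) {
    g <- gradCAM(m, img, 2, "conv_3")
    e <- egradCAM(m, img, 2, "conv_3")
    expect_identical(saliencyGrid(g), saliencyGrid(e))
  }
  # a threshold above every entropy excludes everything: zero map + warning
  expect_warning(z <- egradCAM(m, img, 2, "conv_3",
                               entropyThreshold = 100), "excluded")
  expect_true(all(saliencyGrid(z) == 0))
})

test_that("forcing a channel constant removes it exactly as manual exclusion", {
  net <- tinyUntrainedNet(seed = 33)
  # channel 2 of conv_2: zero weights, negative bias -> constant (0 after relu
  # downstream, constant at the conv output)
  i <- which(layerNames(net$spec) == "conv_2")
  net$params[[i]]$W[, 2] <- 0
  net$params[[i]]$b[2] <- -5
  img <- randomImage(8, seed = 3)
  e <- egradCAM(net, img, 1, "conv_2")
  sg <- saliencyGradients(net, img, 1, "conv_2")
  w <- apply(sg$gradients, 3, mean)
  w[2] <- 0  # manual exclusion of the dead map
  manual <- matrix(0, 4, 4)
  for (k in seq_along(w)) manual <- manual + w[k] * sg$activations[, , k, 1]
  manual <- pmax(manual, 0)
  up <- echonet:::bilinearOperator(4, 8) %*% manual %*%
    t(echonet:::bilinearOperator(4, 8))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  expect_equal(saliencyGrid(e), up, tolerance = 1e-12)
})

test_that("ablation weights match an independent re-scoring loop bit-wise", {
  net <- tinyTrainedModel()
  img <- tinyDataset()$rois[[5]]
  layer <- "conv_3"
  i <- which(layerNames(net$spec) == layer)
  x <- echonet:::imagesToArray(list(img))
  fw <- echonet:::forwardPass(net, x)
  acts <- fw$caches[[i]]$out
  yc <- fw$logits[1, 2]
  # independent tail: affine batchnorm (inference), relu, gap, fc written
  # out longhand from the stored parameters
  tailScore <- function(a) {
    bn <- net$params[[i + 1]]
    C <- dim(a)[3]
    z <- a
    for (c in seq_len(C))
      z[, , c, 1] <- bn$gamma[c] * (a[, , c, 1] - bn$runMean[c]) /
        sqrt(bn$runVar[c] + 1e-5) + bn$beta[c]
    z <- pmax(z, 0)
    feat <- apply(z[, , , 1, drop = FALSE], 3, mean)
    fc <- net$params[[which(layerNames(net$spec) == "fc")]]
    (feat %*% fc$W + fc$b)[1, 2]
  }
  expect_equal(tailScore(acts), yc, tolerance = 1e-10)
  refW <- vapply(seq_len(dim(acts)[3]), function(k) {
    a <- acts; a[, , k, ] <- 0
    (yc - tailScore(a)) / yc
  }, numeric(1))
  pkgW <- vapply(seq_len(dim(acts)[3]), function(k) {
    a <- acts; a[, , k, ] <- 0
    (yc - echonet:::forwardTail(net, i, a)[1, 2]) / yc
  }, numeric(1))
  expect_equal(pkgW, refW, tolerance = 1e-10)
  # repeated calls are bit-identical
  s1 <- ablationCAM(net, img, 2, layer)
  s2 <- ablationCAM(net, img, 2, layer)
  expect_identical(saliencyGrid(s1), saliencyGrid(s2))
  # an identically-zero feature map has ablation weight exactly 0
  az <- acts; az[, , 1, ] <- 0
  netz <- net
  # zeroing via the conv parameters of map 1 makes its activation zero
  netz$params[[i]]$W[, 1] <- 0; netz$params[[i]]$b[1] <- 0
  fwz <- echonet:::forwardPass(netz, x)
  actz <- fwz$caches[[i]]$out
  ycz <- fwz$logits[1, 2]
  yk <- echonet:::forwardTail(netz, i, {a <- actz; a[, , 1, ] <- 0; a})[1, 2]
  expect_identical((ycz - yk) / ycz, 0)
})

test_that("zero-entropy audit counts dead channels exactly", {
  net <- tinyUntrainedNet(seed = 44)
  img <- randomImage(8, seed = 7)
  # all channels active on a random image
  audit <- zeroEntropyRatio(net, img, "conv_2")
  expect_equal(zeroEntropyPercent(audit), 0)
  expect_length(entropies(audit), 8)  # 2nd block of the base-4 backbone
  # force 2 of 8 channels constant
  i <- which(layerNames(net$spec) == "conv_2")
  net$params[[i]]$W[, c(2, 5)] <- 0
  net$params[[i]]$b[c(2, 5)] <- c(-1, 0.3)
  audit2 <- zeroEntropyRatio(net, img, "conv_2")
  expect_equal(zeroEntropyPercent(audit2), 25.00)
  expect_equal(audit2@nZero, 2L)
  tab <- auditTable(audit2)
  expect_equal(which(tab$zero), c(2L, 5L))
})

test_that("CAM targets must be convolutional layers", {
  net <- tinyUntrainedNet()
  img <- randomImage(8, seed = 1)
  expect_error(gradCAM(net, img, 1, "bn_1"), "not convolutional")
  expect_error(gradCAM(net, img, 1, "nope"), "no layer")
  expect_error(zeroEntropyRatio(net, img, "gap"), "not convolutional")
})
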