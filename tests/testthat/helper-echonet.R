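# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# 120 synthetic images (60 per class) at 64px, RoIs resampled to 16px
tinyDataset <- function() {
  if (is.null(.fixtures$tiny)) {
    ds <- generateDataset(60, 60, seed = 424242, imageSize = 64)
    labels <- vapply(ds, lesionLabel, character(1))
    rois <- lapply(ds, function(im) extractRoi(im, 0.08, c(16, 16))$roi)
    .fixtures$tiny <- list(images = ds, labels = labels, rois = rois)
  }
  .fixtures$tiny
}

# narrow B=1 backbone trained on the tiny dataset (for explainability and
# engine tests); deterministic under the fixed seed
tinyTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    d <- tinyDataset()
    hp <- hyperParams(1, "adam", 1e-6, 32, 50)
    spec <- buildArchitecture(hp, inputSize = 16, baseKernels = 8)
    idx <- c(1:50, 61:110)
    vidx <- c(51:60, 111:120)
    .fixtures$model <- trainModel(spec, hp, d$rois[idx], d$labels[idx],
                                  d$rois[vidx], d$labels[vidx],
                                  seed = 99, maxEpochs = 15)
  }
  .fixtures$model
}

# untrained tiny network on 8px inputs for pure-engine checks
tinyUntrainedNet <- function(seed = 3) {
  spec <- buildArchitecture(hyperParams(1, "adam", 1e-6, 32, 50),
                            inputSize = 8, baseKernels = 4)
  initNetwork(spec, seed = seed)
}

randomImage <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}
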