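# Stratified cross-validated training and evaluation.
#
# Folds are stratified so every test fold carries the two classes at the
# dataset's ratio (remainders go to the earliest folds); within each
# fold's training portion, a stratified 10% becomes the validation set.
# Augmentation happens strictly after the split and only on the training
# and validation members, so no derived copy of a test image can leak
# into training.  The malignant class is the positive class throughout.

#' Stratified k-fold splits with a validation carve-out
#'
#' Deterministically (for a fixed seed) partitions the dataset into `k`
#' test folds with per-class counts differing by at most one across folds,
#' and splits each fold's remaining examples into training and a
#' stratified validation subset.
#'
#' @param labels class labels (`"benign"`/`"malignant"` or any two-level
#'   vector); every class needs at least `k` members.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param valFraction fraction of the non-test examples allocated to
#'   validation, stratified (default 0.1).
#' @return list of `k` fold splits, each a list with `fold`, `train`,
#'   `validation` and `test` index vectors.  The `test` lists partition
#'   the dataset.
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L, valFraction = 0.1) {
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("every class needs at least k=%d members", k))
  withSeed(seed, {
    foldOf <- integer(length(labels))
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      sizes <- rep(n %/% k, k)
      if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      foldOf[idx] <- rep(seq_len(k), times = sizes)
    }
    lapply(seq_len(k), function(f) {
      test <- which(foldOf == f)
      rest <- which(foldOf != f)
      val <- integer(0)
      for (cl in classes) {
        restCl <- rest[labels[rest] == cl]
        nVal <- round(valFraction * length(restCl))
        if (nVal > 0L) val <- c(val, sample(restCl, nVal))
      }
      val <- sort(val)
      list(fold = f, train = setdiff(rest, val), validation = val,
           test = test)
    })
  })
}

#' Metrics from confusion counts
#'
#' @param TP,FP,TN,FN confusion counts with malignant as the positive
#'   class.
#' @return a [Metrics-class].
#' @examples
#' metricsFromCounts(TP = 50, FN = 10, TN = 40, FP = 20)
#' @export
metricsFromCounts <- function(TP, FP, TN, FN) {
  total <- TP + FP + TN + FN
  methods::new("Metrics",
    TP = as.integer(TP), FP = as.integer(FP),
    TN = as.integer(TN), FN = as.integer(FN),
    sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
    accuracy = if (total > 0) 100 * (TP + TN) / total else NA_real_)
}

#' Compute classification metrics from predictions
#'
#' Sensitivity is malignant recall, specificity benign recall, accuracy
#' the overall fraction correct (all in percent).
#'
#' @param predictions,labels equal-length vectors with values `"benign"`
#'   or `"malignant"`.
#' @return a [Metrics-class].
#' @export
computeMetrics <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels))
    stop("predictions and labels must be non-empty and of equal length")
  pos <- "malignant"
  metricsFromCounts(
    TP = sum(predictions == pos & labels == pos),
    FP = sum(predictions == pos & labels != pos),
    TN = sum(predictions != pos & labels != pos),
    FN = sum(predictions != pos & labels == pos))
}

#' Select the best fold of a cross-validation
#'
#' Maximal accuracy; ties broken by the smaller absolute
#' sensitivity-specificity gap, residual ties by the lowest fold index.
#'
#' @param results a [CVResult-class] or a list of [Metrics-class].
#' @return the selected fold index.
#' @export
selectBest <- function(results) {
  perFold <- if (methods::is(results, "CVResult")) results@perFold else results
  stopifnot(length(perFold) >= 1L)
  acc <- vapply(perFold, accuracy, numeric(1))
  gap <- vapply(perFold, balanceGap, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1L) best <- best[gap[best] == min(gap[best])]
  best[1]
}

#' Absolute sensitivity-specificity gap
#'
#' @param metrics a [Metrics-class] (or a named vector with
#'   `sensitivity` and `specificity` percentages).
#' @return `|sensitivity - specificity|` in percentage points.
#' @export
balanceGap <- function(metrics) {
  v <- metricsVector(metrics)
  unname(abs(v["sensitivity"] - v["specificity"]))
}

metricsVector <- function(m) {
  if (methods::is(m, "Metrics"))
    c(sensitivity = sensitivity(m), specificity = specificity(m),
      accuracy = accuracy(m))
  else m[c("sensitivity", "specificity", "accuracy")]
}

#' Generalization gap between internal and external tests
#'
#' Signed internal-minus-external difference per metric; a positive
#' accuracy gap means the model performs worse on the external
#' (unseen-source) data.
#'
#' @param internal,external [Metrics-class] objects (or named vectors
#'   with `sensitivity`, `specificity`, `accuracy` percentages).
#' @return named numeric vector of the three signed differences.
#' @examples
#' generalizationGap(
#'   c(sensitivity = 84.42, specificity = 84.26, accuracy = 85.19),
#'   c(sensitivity = 81.84, specificity = 84.20, accuracy = 83.33))
#' @export
generalizationGap <- function(internal, external) {
  metricsVector(internal) - metricsVector(external)
}

#' Augmented training pool with provenance
#'
#' Expands the selected images with their four augmented variants
#' ([augmentRoi()]); the returned provenance table records, for every
#' pooled image, the source index in the full dataset and the generating
#' operator, making leakage checks against a held-out fold directly
#' assertable.
#'
#' @param rois list of RoI matrices for the whole dataset.
#' @param labels labels parallel to `rois`.
#' @param idx indices to pool (training + validation members).
#' @param augment apply augmentation (`TRUE`) or pool originals only.
#' @return list with `images`, `labels` and a `provenance` data.frame
#'   (columns `source`, `op`).
#' @export
buildTrainingPool <- function(rois, labels, idx, augment = TRUE) {
  images <- list(); lab <- character(0)
  src <- integer(0); op <- character(0)
  for (i in idx) {
    images <- c(images, list(rois[[i]]))
    lab <- c(lab, labels[i]); src <- c(src, i); op <- c(op, "original")
    if (augment) {
      as <- augmentRoi(rois[[i]])
      images <- c(images, as@augmented)
      lab <- c(lab, rep(labels[i], 4L))
      src <- c(src, rep(i, 4L)); op <- c(op, as@provenance)
    }
  }
  list(images = images, labels = lab,
       provenance = data.frame(source = src, op = op,
                               stringsAsFactors = FALSE))
}

#' Stratified k-fold cross-validated training and evaluation
#'
#' For each fold: augment the training and validation members (test
#' images stay original), train a backbone under `hp`, and evaluate on
#' the held-out originals.  Reports per-fold metrics, their mean and
#' standard deviation, and the selected fold per [selectBest()].
#'
#' @param rois list of RoI matrices (all `inputSize x inputSize`).
#' @param labels labels parallel to `rois`.
#' @param hp a [HyperParams-class].
#' @param k number of folds.
#' @param seed master seed (splits, weight init, batch order).
#' @param baseKernels optional narrow-backbone override passed to
#'   [buildArchitecture()].
#' @param augment augment training/validation pools (default `TRUE`).
#' @param maxEpochs optional epoch cap for smoke-scale runs.
#' @param learnRate learning rate (default 1e-4).
#' @param keepModels retain the trained model of every fold.
#' @return a [CVResult-class]; the fold splits are attached as
#'   `attr(result, "folds")` and pooling provenance per fold as
#'   `attr(result, "provenance")`.
#' @export
crossValidate <- function(rois, labels, hp, k = 10L, seed = 1L,
                          baseKernels = NULL, augment = TRUE,
                          maxEpochs = NULL, learnRate = 1e-4,
                          keepModels = FALSE) {
  stopifnot(length(rois) == length(labels))
  inputSize <- nrow(rois[[1]])
  spec <- buildArchitecture(hp, inputSize = inputSize,
                            baseKernels = baseKernels)
  folds <- stratifiedFolds(labels, k = k, seed = seed)
  perFold <- vector("list", k)
  models <- list()
  provenance <- vector("list", k)
  for (f in seq_len(k)) {
    fs <- folds[[f]]
    pool <- buildTrainingPool(rois, labels, fs$train, augment = augment)
    valPool <- buildTrainingPool(rois, labels, fs$validation,
                                 augment = augment)
    provenance[[f]] <- rbind(
      if (nrow(pool$provenance) > 0L)
        cbind(pool$provenance, role = "train"),
      if (nrow(valPool$provenance) > 0L)
        cbind(valPool$provenance, role = "validation"))
    model <- trainModel(spec, hp, pool$images, pool$labels,
                        valPool$images, valPool$labels,
                        seed = deriveSeed(seed, f),
                        learnRate = learnRate, maxEpochs = maxEpochs)
    pred <- predictModel(model, rois[fs$test])$class
    perFold[[f]] <- computeMetrics(pred, labels[fs$test])
    if (keepModels) models[[f]] <- model
  }
  statsM <- sapply(perFold, metricsVector)
  res <- methods::new("CVResult",
    perFold = perFold,
    means = rowMeans(statsM),
    sds = apply(statsM, 1, stats::sd),
    selectedFold = as.integer(selectBest(perFold)),
    models = models)
  attr(res, "folds") <- folds
  attr(res, "provenance") <- provenance
  res
}
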