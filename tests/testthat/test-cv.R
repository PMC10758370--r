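# Stratified folds, metrics, model selection, generalization gap.

test_that("stratified folds partition the data with balanced class counts", {
  labels <- c(rep("benign", 1012), rep("malignant", 870))
  folds <- stratifiedFolds(labels, k = 10, seed = 1)
  testSizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(testSizes %in% c(188L, 189L)))
  malPerFold <- vapply(folds, function(f)
    sum(labels[f$test] == "malignant"), integer(1))
  expect_true(all(malPerFold == 87L))
  allTest <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(allTest, seq_along(labels))
  # train / validation / test are disjoint within every fold
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    # validation is ~10% of the non-test examples, stratified
    expect_equal(length(f$validation),
                 round(0.1 * sum(labels[f$validation] == "benign") * 10) +
                   round(0.1 * sum(labels[f$validation] == "malignant") * 10),
                 tolerance = 2)
  }
})

test_that("exactly divisible classes give exactly equal folds", {
  labels <- rep(c("benign", "malignant"), each = 10)
  folds <- stratifiedFolds(labels, k = 10, seed = 2)
  for (f in folds) {
    expect_length(f$test, 2)
    expect_setequal(labels[f$test], c("benign", "malignant"))
  }
})

test_that("folds are deterministic per seed and reject sparse classes", {
  labels <- rep(c("benign", "malignant"), each = 30)
  f1 <- stratifiedFolds(labels, k = 5, seed = 9)
  f2 <- stratifiedFolds(labels, k = 5, seed = 9)
  expect_identical(f1, f2)
  expect_error(stratifiedFolds(c(rep("benign", 30), rep("malignant", 3)),
                               k = 5), "at least k")
})

test_that("metrics follow their defining ratios", {
  m <- metricsFromCounts(TP = 50, FN = 10, TN = 40, FP = 20)
  expect_equal(sensitivity(m), 83.33, tolerance = 1e-2)
  expect_equal(specificity(m), 66.67, tolerance = 1e-2)
  expect_equal(accuracy(m), 75.00, tolerance = 1e-12)

  perfect <- computeMetrics(rep(c("benign", "malignant"), 5),
                            rep(c("benign", "malignant"), 5))
  expect_equal(c(sensitivity(perfect), specificity(perfect),
                 accuracy(perfect)), c(100, 100, 100))

  allBenign <- computeMetrics(rep("benign", 10),
                              rep(c("benign", "malignant"), 5))
  expect_equal(sensitivity(allBenign), 0)
  expect_equal(specificity(allBenign), 100)

  expect_error(computeMetrics(character(0), character(0)), "non-empty")
})

test_that("fold selection maximises accuracy then balance then index", {
  mk <- function(sens, spec) {
    tp <- round(sens); fn <- 100 - tp; tn <- round(spec); fp <- 100 - tn
    metricsFromCounts(tp, fp, tn, fn)
  }
  expect_equal(selectBest(list(mk(88, 88))), 1)
  # equal accuracy, second has the better balance
  a <- metricsFromCounts(TP = 91, FN = 9, TN = 85, FP = 15)   # acc 88, gap 6
  b <- metricsFromCounts(TP = 89, FN = 11, TN = 87, FP = 13)  # acc 88, gap 2
  expect_equal(selectBest(list(a, b)), 2)
  # accuracy dominates the balance criterion
  hi <- metricsFromCounts(TP = 95, FN = 5, TN = 85, FP = 15)  # acc 90, gap 10
  lo <- metricsFromCounts(TP = 88, FN = 12, TN = 88, FP = 12) # acc 88, gap 0
  expect_equal(selectBest(list(hi, lo)), 1)
  # full tie falls back to the lowest fold index
  expect_equal(selectBest(list(mk(80, 90), mk(80, 90))), 1)
})

test_that("generalization gap is a signed per-metric difference", {
  int <- c(sensitivity = 84.42, specificity = 84.26, accuracy = 85.19)
  ext <- c(sensitivity = 81.84, specificity = 84.20, accuracy = 83.33)
  gap <- generalizationGap(int, ext)
  expect_equal(unname(gap["accuracy"]), 1.86, tolerance = 1e-9)
  expect_equal(generalizationGap(int, int), c(sensitivity = 0,
                                              specificity = 0, accuracy = 0))
  expect_equal(generalizationGap(ext, int), -gap)
})

test_that("balance gap reproduces printed model and reader gaps", {
  expect_equal(balanceGap(c(sensitivity = 81.84, specificity = 84.20,
                            accuracy = NA)),
               2.36, tolerance = 1e-9)
  m <- metricsFromCounts(TP = 50, FN = 10, TN = 40, FP = 20)
  expect_equal(balanceGap(m), abs(sensitivity(m) - specificity(m)))
  eq <- metricsFromCounts(TP = 50, FN = 50, TN = 50, FP = 50)
  expect_equal(balanceGap(eq), 0)
})

test_that("cross-validation summarises folds and guards against leakage", {
  d <- tinyDataset()
  hp <- hyperParams(1, "adam", 1e-6, 32, 50)
  cv <- crossValidate(d$rois, d$labels, hp, k = 3, seed = 77,
                      baseKernels = 4, maxEpochs = 4)
  expect_length(cv@perFold, 3)
  # stored mean/sd recompute from the per-fold metrics
  acc <- vapply(cv@perFold, accuracy, numeric(1))
  expect_equal(unname(cv@means["accuracy"]), mean(acc), tolerance = 1e-9)
  expect_equal(unname(cv@sds["accuracy"]), sd(acc), tolerance = 1e-9)
  expect_equal(cv@selectedFold, selectBest(cv@perFold))
  # leakage guard: no augmented (or original) copy of a test image in the
  # fold's training/validation pool, by provenance
  folds <- attr(cv, "folds")
  prov <- attr(cv, "provenance")
  for (f in 1:3)
    expect_length(intersect(prov[[f]]$source, folds[[f]]$test), 0)
})
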