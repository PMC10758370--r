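# Run configuration and the end-to-end pipeline.
#
# A run config bundles every knob of the experimental loop with defaults
# at the method's canonical values: search budget 50 with 4 seed points,
# tenfold stratified cross-validation, 8% RoI margin and SVD ratios
# 25/35/45%.  The pipeline chains simulate -> roi -> (augment inside the
# CV) -> search -> crossval -> gap -> explain under one master seed and
# writes every artifact into a report directory with an append-only log.

#' Build a run configuration
#'
#' Defaults are the method's canonical settings; the synthetic-data,
#' network-width and epoch knobs default to desk-scale values suitable
#' for CPU runs and are stated in every report.
#'
#' @param masterSeed master seed for the whole run.
#' @param nBenign,nMalignant synthetic per-class image counts.
#' @param imageSize synthetic image side (pixels).
#' @param inputSize network input side (pixels, divisible by 4).
#' @param roiMargin RoI margin fraction (default 0.08).
#' @param svdRatios SVD retained fractions (default `c(0.25, 0.35,
#'   0.45)`).
#' @param budget,nSeed Bayesian-optimisation budget and seed points
#'   (defaults 50 and 4).
#' @param k cross-validation folds (default 10).
#' @param baseKernels first-block kernel count override (`NULL` uses the
#'   kernel rule).
#' @param searchEpochs epoch cap per search evaluation.
#' @param cvEpochs epoch cap per cross-validation fold.
#' @param nExternalBenign,nExternalMalignant synthetic external test set
#'   counts used for the generalization gap.
#' @param runSearch run the architecture search stage (`TRUE`) or use
#'   `hp` directly.
#' @param hp hyperparameter setting used when `runSearch = FALSE`
#'   (default [optimalHyperParams()]).
#' @return a named list of class `echonetConfig`.
#' @export
runConfig <- function(masterSeed = 1L,
                      nBenign = 50L, nMalignant = 50L,
                      imageSize = 64L, inputSize = 32L,
                      roiMargin = 0.08,
                      svdRatios = c(0.25, 0.35, 0.45),
                      budget = 50L, nSeed = 4L, k = 10L,
                      baseKernels = 8L,
                      searchEpochs = 5L, cvEpochs = 10L,
                      nExternalBenign = 20L, nExternalMalignant = 20L,
                      runSearch = FALSE, hp = optimalHyperParams()) {
  stopifnot(budget >= nSeed, k >= 2L, roiMargin >= 0, roiMargin < 1)
  structure(list(masterSeed = as.integer(masterSeed),
                 nBenign = as.integer(nBenign),
                 nMalignant = as.integer(nMalignant),
                 imageSize = as.integer(imageSize),
                 inputSize = as.integer(inputSize),
                 roiMargin = roiMargin, svdRatios = svdRatios,
                 budget = as.integer(budget), nSeed = as.integer(nSeed),
                 k = as.integer(k), baseKernels = baseKernels,
                 searchEpochs = as.integer(searchEpochs),
                 cvEpochs = as.integer(cvEpochs),
                 nExternalBenign = as.integer(nExternalBenign),
                 nExternalMalignant = as.integer(nExternalMalignant),
                 runSearch = isTRUE(runSearch), hp = hp),
            class = "echonetConfig")
}

#' @export
print.echonetConfig <- function(x, ...) {
  cat(sprintf("echonet run config (seed %d, hash %s)\n", x$masterSeed,
              configHash(x)))
  cat(sprintf("  data: %d benign + %d malignant @ %dpx -> input %dpx\n",
              x$nBenign, x$nMalignant, x$imageSize, x$inputSize))
  cat(sprintf("  search: budget %d, %d seed points (%s); CV: %d folds\n",
              x$budget, x$nSeed,
              if (x$runSearch) "enabled" else "disabled", x$k))
  invisible(x)
}

configToJson <- function(config) {
  c2 <- unclass(config)
  c2$hp <- list(B = config$hp@B, Opt = config$hp@Opt, Lr = config$hp@Lr,
                Mn = config$hp@Mn, Epo = config$hp@Epo)
  jsonlite::toJSON(c2, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Stable hash of a run configuration
#'
#' FNV-1a over the canonical JSON rendering; used to tag every output
#' file of a run so metrics can be traced back to their exact settings.
#'
#' @param config an `echonetConfig`.
#' @return 8-hex-digit hash string.
#' @export
configHash <- function(config) {
  bytes <- utf8ToInt(as.character(configToJson(config)))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

logLine <- function(logPath, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  cat(line, "\n", file = logPath, append = TRUE, sep = "")
  invisible(line)
}

#' Run the full pipeline and emit a report directory
#'
#' Executes simulate, RoI extraction, (optionally) the architecture
#' search, cross-validated training with in-fold augmentation, external
#' evaluation with generalization gaps, and the saliency/entropy audit,
#' all under the config's master seed.  Writes `config.json`, `log.txt`,
#' a dataset manifest, per-fold metrics (`metrics.csv`), the search
#' history (`history.json`), the selected architecture
#' (`architecture.json`), gap and audit tables and a `report.json`
#' summary into `outDir`.
#'
#' @param config an `echonetConfig`.
#' @param outDir report directory (created; existing files overwritten).
#' @return invisibly, a list with the main in-memory results
#'   (`cv`, `externalMetrics`, `gaps`, `audit`, `history`, paths).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "echonetConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  cat("", file = logPath)
  hash <- configHash(config)
  writeLines(as.character(configToJson(config)),
             file.path(outDir, "config.json"))
  logLine(logPath, "config", sprintf("seed=%d hash=%s", config$masterSeed,
                                     hash))
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed (seed %d): %s", stage,
                 config$masterSeed, conditionMessage(e)), call. = FALSE)

  # -- simulate ------------------------------------------------------------
  images <- tryCatch(
    generateDataset(config$nBenign, config$nMalignant,
                    seed = config$masterSeed,
                    imageSize = config$imageSize),
    error = function(e) fail("simulate", e))
  labels <- vapply(images, lesionLabel, character(1))
  manifest <- datasetManifest("internal",
                              benign = sum(labels == "benign"),
                              malignant = sum(labels == "malignant"),
                              source = "synthetic")
  writeManifest(manifest, file.path(outDir, "manifest.json"))
  logLine(logPath, "simulate", sprintf("%d images (%d benign, %d malignant)",
                                       length(images),
                                       sum(labels == "benign"),
                                       sum(labels == "malignant")))

  # -- roi -----------------------------------------------------------------
  rois <- tryCatch(
    lapply(images, function(im)
      extractRoi(im, fraction = config$roiMargin,
                 target = c(config$inputSize, config$inputSize))$roi),
    error = function(e) fail("roi", e))
  logLine(logPath, "roi", sprintf("%d RoIs at %dx%d (margin %.2f)",
                                  length(rois), config$inputSize,
                                  config$inputSize, config$roiMargin))

  # -- search --------------------------------------------------------------
  history <- NULL
  hp <- config$hp
  if (config$runSearch) {
    splitSeed <- deriveSeed(config$masterSeed, 11L)
    split <- stratifiedFolds(labels, k = 5L, seed = splitSeed)[[1]]
    objective <- function(h) {
      sp <- buildArchitecture(h, inputSize = config$inputSize,
                              baseKernels = config$baseKernels)
      m <- trainModel(sp, h, rois[split$train], labels[split$train],
                      rois[split$validation], labels[split$validation],
                      seed = deriveSeed(config$masterSeed, 13L),
                      maxEpochs = config$searchEpochs)
      m$finalValError
    }
    history <- tryCatch(
      runSearch(objective, budget = config$budget, nSeed = config$nSeed,
                seed = deriveSeed(config$masterSeed, 17L)),
      error = function(e) fail("search", e))
    hp <- bestObservation(history)$hp
    historyToJson(history, file.path(outDir, "history.json"))
    logLine(logPath, "search",
            sprintf("budget %d done; best error %.4f", config$budget,
                    bestObservation(history)$error))
  } else {
    logLine(logPath, "search", "skipped (config hp used)")
  }
  spec <- buildArchitecture(hp, inputSize = config$inputSize,
                            baseKernels = config$baseKernels)
  architectureToJson(spec, file.path(outDir, "architecture.json"))
  utils::write.csv(complexityReport(spec, model = "backbone"),
                   file.path(outDir, "complexity.csv"), row.names = FALSE)

  # -- crossval ------------------------------------------------------------
  cv <- tryCatch(
    crossValidate(rois, labels, hp, k = config$k,
                  seed = deriveSeed(config$masterSeed, 23L),
                  baseKernels = config$baseKernels,
                  maxEpochs = config$cvEpochs, keepModels = TRUE),
    error = function(e) fail("crossval", e))
  foldTab <- do.call(rbind, lapply(seq_along(cv@perFold), function(f) {
    m <- cv@perFold[[f]]
    data.frame(fold = f, TP = m@TP, FP = m@FP, TN = m@TN, FN = m@FN,
               sensitivity = m@sensitivity, specificity = m@specificity,
               accuracy = m@accuracy, seed = config$masterSeed,
               config_hash = hash)
  }))
  utils::write.csv(foldTab, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  logLine(logPath, "crossval",
          sprintf("mean accuracy %.2f%% (fold %d selected)",
                  cv@means["accuracy"], cv@selectedFold))

  # -- gap -----------------------------------------------------------------
  selected <- cv@models[[cv@selectedFold]]
  extImages <- tryCatch(
    generateDataset(config$nExternalBenign, config$nExternalMalignant,
                    seed = deriveSeed(config$masterSeed, 29L),
                    imageSize = config$imageSize),
    error = function(e) fail("gap", e))
  extLabels <- vapply(extImages, lesionLabel, character(1))
  extRois <- lapply(extImages, function(im)
    extractRoi(im, fraction = config$roiMargin,
               target = c(config$inputSize, config$inputSize))$roi)
  extMetrics <- computeMetrics(predictModel(selected, extRois)$class,
                               extLabels)
  gapSelected <- generalizationGap(cv@perFold[[cv@selectedFold]], extMetrics)
  gapAverage <- generalizationGap(cv@means, metricsVector(extMetrics))
  gapTab <- data.frame(variant = c("selected", "average"),
                       rbind(gapSelected, gapAverage),
                       row.names = NULL)
  utils::write.csv(gapTab, file.path(outDir, "gap.csv"), row.names = FALSE)
  logLine(logPath, "gap", sprintf("selected-model accuracy gap %.2f",
                                  gapSelected["accuracy"]))

  # -- explain -------------------------------------------------------------
  lastConv <- sprintf("conv_%d", spec@nConvLayers)
  probe <- extRois[[1]]
  classIdx <- match(extLabels[1], c("benign", "malignant"))
  audit <- tryCatch(
    zeroEntropyRatio(selected, probe, lastConv),
    error = function(e) fail("explain", e))
  utils::write.csv(auditTable(audit), file.path(outDir, "audit.csv"),
                   row.names = FALSE)
  sal <- gradCAM(selected, probe, classIdx, lastConv)
  png::writePNG(cbind(probe, saliencyGrid(sal)),
                file.path(outDir, "saliency.png"))
  logLine(logPath, "explain",
          sprintf("zero-entropy ratio %.2f%% at %s",
                  zeroEntropyPercent(audit), lastConv))

  # -- report --------------------------------------------------------------
  pooled <- poolManifest(manifest, "internal")
  report <- list(seed = config$masterSeed, config_hash = hash,
                 pooled_counts = as.list(pooled),
                 cv_means = as.list(cv@means), cv_sds = as.list(cv@sds),
                 selected_fold = cv@selectedFold,
                 external = as.list(metricsVector(extMetrics)),
                 gap_selected = as.list(gapSelected),
                 gap_average = as.list(gapAverage),
                 zero_entropy_ratio = zeroEntropyPercent(audit))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine(logPath, "report", "complete")
  invisible(list(cv = cv, externalMetrics = extMetrics,
                 gaps = gapTab, audit = audit, history = history,
                 spec = spec, outDir = outDir))
}
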