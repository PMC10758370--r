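# S4 class definitions.  Constructors with argument checking live next to
# each module's operations; validity methods here enforce the structural
# invariants that every downstream stage relies on.

#' Axis-aligned pixel rectangle
#'
#' Rectangles are 0-based and half-open: a `Rect` covers pixel columns
#' `[xMin, xMax)` and rows `[yMin, yMax)`.  Width is `xMax - xMin`, height
#' `yMax - yMin`.
#'
#' @slot xMin,yMin,xMax,yMax integer pixel coordinates.
#' @seealso [rect()], [boundingRect()], [expandRect()]
#' @export
setClass("Rect",
  representation(xMin = "integer", yMin = "integer",
                 xMax = "integer", yMax = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@xMin) != 1L || length(object@yMin) != 1L ||
        length(object@xMax) != 1L || length(object@yMax) != 1L)
      msg <- c(msg, "all coordinates must be scalar")
    else {
      if (object@xMin >= object@xMax) msg <- c(msg, "xMin must be < xMax")
      if (object@yMin >= object@yMax) msg <- c(msg, "yMin must be < yMax")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Parametric description of one synthetic lesion image
#'
#' A `LesionSpec` fixes everything about a synthetic ultrasound-like image
#' except the realisation of the speckle noise: class label, geometry of
#' the elliptical lesion, boundary irregularity, interior and background
#' echogenicity, posterior acoustic effect and speckle strength.
#'
#' Benign and malignant specs are separated by boundary irregularity:
#' benign lesions have `irregularity` below [irregularityThreshold()],
#' malignant lesions above it.  Lesions are hypo-/anechoic, so
#' `interiorLevel < backgroundLevel` is enforced.
#'
#' @slot label `"benign"` or `"malignant"`.
#' @slot imageSize side of the square image in pixels (>= 64).
#' @slot center numeric length-2, lesion centre `(x, y)` in 0-based pixels.
#' @slot radii numeric length-2, ellipse radii `(rx, ry)` in pixels.
#' @slot irregularity non-negative amplitude of the radial boundary
#'   perturbation (dimensionless, relative to the local radius).
#' @slot interiorLevel,backgroundLevel relative intensities in `[0, 1]`.
#' @slot posteriorEffect `"enhancement"`, `"shadowing"` or `"none"`.
#' @slot posteriorStrength strength of the posterior effect in `[0, 1]`.
#' @slot speckleStrength multiplicative speckle coefficient (>= 0); the
#'   standard deviation of the unit-mean gamma noise field.
#' @export
setClass("LesionSpec",
  representation(label = "character", imageSize = "integer",
                 center = "numeric", radii = "numeric",
                 irregularity = "numeric",
                 interiorLevel = "numeric", backgroundLevel = "numeric",
                 posteriorEffect = "character", posteriorStrength = "numeric",
                 speckleStrength = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@label %in% c("benign", "malignant"))
      msg <- c(msg, "label must be 'benign' or 'malignant'")
    if (object@imageSize < 64L)
      msg <- c(msg, "imageSize must be >= 64")
    if (length(object@center) != 2L || length(object@radii) != 2L)
      msg <- c(msg, "center and radii must have length 2")
    if (any(object@radii <= 0))
      msg <- c(msg, "radii must be positive")
    if (object@irregularity < 0)
      msg <- c(msg, "irregularity must be >= 0")
    if (object@interiorLevel < 0 || object@interiorLevel > 1 ||
        object@backgroundLevel < 0 || object@backgroundLevel > 1)
      msg <- c(msg, "intensity levels must lie in [0, 1]")
    if (object@interiorLevel >= object@backgroundLevel)
      msg <- c(msg, "interiorLevel must be < backgroundLevel (hypoechoic lesion)")
    if (!object@posteriorEffect %in% c("enhancement", "shadowing", "none"))
      msg <- c(msg, "posteriorEffect must be enhancement/shadowing/none")
    if (object@posteriorStrength < 0 || object@posteriorStrength > 1)
      msg <- c(msg, "posteriorStrength must lie in [0, 1]")
    if (object@speckleStrength < 0)
      msg <- c(msg, "speckleStrength must be >= 0")
    # class-dependent irregularity separation
    thr <- 0.08
    if (length(msg) == 0L) {
      if (object@label == "benign" && object@irregularity >= thr)
        msg <- c(msg, sprintf("benign specs need irregularity < %.2f", thr))
      if (object@label == "malignant" && object@irregularity < thr)
        msg <- c(msg, sprintf("malignant specs need irregularity >= %.2f", thr))
      # lesion (including maximal boundary excursion) must fit inside image
      reach <- max(object@radii) * (1 + object@irregularity)
      if (object@center[1] - reach < 0 || object@center[2] - reach < 0 ||
          object@center[1] + reach > object@imageSize - 1 ||
          object@center[2] + reach > object@imageSize - 1)
        msg <- c(msg, "lesion extends outside the image")
    }
    if (is.null(msg)) TRUE else msg
  })

#' A synthetic or imported lesion image with its annotation
#'
#' Couples a grayscale pixel matrix (values in `[0, 1]`, `[row, col]`
#' indexing) with the ordered lesion boundary annotation, the class label
#' and the seed used to realise it.
#'
#' @slot pixels numeric matrix in `[0, 1]`.
#' @slot boundaryPoints numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates), at least 8 ordered contour points, all strictly inside
#'   the image extent.
#' @slot label `"benign"` or `"malignant"`.
#' @slot seed integer provenance seed.
#' @slot spec the generating [LesionSpec-class] (empty list for imported
#'   images).
#' @export
setClass("AnnotatedImage",
  representation(pixels = "matrix", boundaryPoints = "matrix",
                 label = "character", seed = "integer", spec = "list"),
  validity = function(object) {
    msg <- NULL
    px <- object@pixels
    if (!is.numeric(px)) msg <- c(msg, "pixels must be numeric")
    else if (any(px < 0 | px > 1)) msg <- c(msg, "pixel values must lie in [0, 1]")
    bp <- object@boundaryPoints
    if (ncol(bp) != 2L) msg <- c(msg, "boundaryPoints must have 2 columns (x, y)")
    else {
      if (nrow(bp) < 8L) msg <- c(msg, "need at least 8 boundary points")
      if (any(bp[, 1] < 0) || any(bp[, 1] > ncol(px) - 1) ||
          any(bp[, 2] < 0) || any(bp[, 2] > nrow(px) - 1))
        msg <- c(msg, "boundary points must lie strictly inside the image")
    }
    if (!object@label %in% c("benign", "malignant"))
      msg <- c(msg, "label must be 'benign' or 'malignant'")
    if (is.null(msg)) TRUE else msg
  })

#' Searched hyperparameter setting
#'
#' The five optimisable hyperparameters of the backbone family: the
#' block-repeat count `B` (number of convolutional layers per block, 1-5),
#' the solver `Opt` (adam / sgdm / rmsprop), the L2-regularization
#' coefficient `Lr` (1e-10 to 1e-2), the mini-batch size `Mn` (32/64/128)
#' and the maximum number of epochs `Epo` (50-250).
#'
#' @slot B integer in `[1, 5]`.
#' @slot Opt one of `"adam"`, `"sgdm"`, `"rmsprop"`.
#' @slot Lr numeric L2 coefficient in `[1e-10, 1e-2]`.
#' @slot Mn integer, one of 32, 64, 128.
#' @slot Epo integer in `[50, 250]`.
#' @export
setClass("HyperParams",
  representation(B = "integer", Opt = "character", Lr = "numeric",
                 Mn = "integer", Epo = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@B < 1L || object@B > 5L) msg <- c(msg, "B must lie in [1, 5]")
    if (!object@Opt %in% c("adam", "sgdm", "rmsprop"))
      msg <- c(msg, "Opt must be adam, sgdm or rmsprop")
    if (object@Lr < 1e-10 || object@Lr > 1e-2)
      msg <- c(msg, "Lr must lie in [1e-10, 1e-2]")
    if (!object@Mn %in% c(32L, 64L, 128L))
      msg <- c(msg, "Mn must be one of 32, 64, 128")
    if (object@Epo < 50L || object@Epo > 250L)
      msg <- c(msg, "Epo must lie in [50, 250]")
    if (is.null(msg)) TRUE else msg
  })

#' Concrete backbone architecture
#'
#' The layer-by-layer realisation of a hyperparameter setting: three
#' blocks, each repeating (conv3x3 -> batchnorm -> relu) `B` times, 2x2
#' stride-2 max-pooling after blocks 1 and 2, then global average pooling,
#' a 2-unit fully connected layer and softmax.  Kernel counts per block are
#' `k, 2k, 4k` with `k = kernelCount(B)`.
#'
#' @slot layers list of layer descriptors (`kind`, `name`, plus
#'   kernel/stride/padding fields for convolutions).
#' @slot inputSize spatial side of the (square) input in pixels.
#' @slot channels input channel count (1 for grayscale).
#' @slot B block-repeat count the spec was built from.
#' @slot baseKernels first-block kernel count.
#' @slot nConvLayers,finalBlockKernels,nParameters derived counts.
#' @export
setClass("ArchitectureSpec",
  representation(layers = "list", inputSize = "integer", channels = "integer",
                 B = "integer", baseKernels = "integer",
                 nConvLayers = "integer", finalBlockKernels = "integer",
                 nParameters = "numeric"),
  validity = function(object) {
    msg <- NULL
    kinds <- vapply(object@layers, `[[`, character(1), "kind")
    if (sum(kinds == "conv3x3") != 3L * object@B)
      msg <- c(msg, "conv layer count must equal 3B")
    if (sum(kinds == "maxpool2x2") != 2L)
      msg <- c(msg, "exactly two max-pooling layers expected")
    tail3 <- utils::tail(kinds, 3)
    if (!identical(tail3, c("gap", "fc", "softmax")))
      msg <- c(msg, "tail must be gap -> fc -> softmax")
    if (is.null(msg)) TRUE else msg
  })

#' History of a Bayesian-optimisation search
#'
#' Ordered record of every evaluated hyperparameter setting together with
#' its objective value (classification error in `[0, 1]`), the encoded
#' search-space point, the master seed and the best-so-far trace.
#'
#' @slot observations list; each element has fields `hp` (a
#'   [HyperParams-class]), `point` (encoded numeric vector) and `error`.
#' @slot seed master seed of the run.
#' @slot bestSoFar numeric, cumulative minimum of the error sequence.
#' @slot bestIndex index of the best observation.
#' @export
setClass("SearchHistory",
  representation(observations = "list", seed = "integer",
                 bestSoFar = "numeric", bestIndex = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@observations)
    errs <- vapply(object@observations, `[[`, numeric(1), "error")
    if (n > 0L) {
      if (any(!is.finite(errs)) || any(errs < 0 | errs > 1))
        msg <- c(msg, "errors must be finite and in [0, 1]")
      if (length(object@bestSoFar) != n)
        msg <- c(msg, "bestSoFar must have one entry per observation")
      else if (any(diff(object@bestSoFar) > 0))
        msg <- c(msg, "bestSoFar must be non-increasing")
      if (length(object@bestIndex) == 1L &&
          !isTRUE(all.equal(errs[object@bestIndex], min(errs))))
        msg <- c(msg, "bestIndex must point at the minimal error")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Binary classification metrics
#'
#' Confusion counts with the malignant class as positive, plus the derived
#' percentages: sensitivity `100 TP/(TP+FN)` (malignant recall),
#' specificity `100 TN/(TN+FP)` (benign recall) and overall accuracy.
#'
#' @slot TP,FP,TN,FN integer confusion counts.
#' @slot sensitivity,specificity,accuracy percentages in `[0, 100]`.
#' @export
setClass("Metrics",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer",
                 sensitivity = "numeric", specificity = "numeric",
                 accuracy = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@TP, object@FP, object@TN, object@FN) < 0L))
      msg <- c(msg, "counts must be non-negative")
    pct <- c(object@sensitivity, object@specificity, object@accuracy)
    if (any(!is.na(pct) & (pct < 0 | pct > 100)))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (is.null(msg)) TRUE else msg
  })

#' Cross-validation result
#'
#' Per-fold [Metrics-class] together with their mean and standard deviation
#' and the fold selected as the best model (maximal accuracy, ties broken
#' by the smaller sensitivity-specificity gap, then by fold index).
#'
#' @slot perFold list of [Metrics-class], one per fold.
#' @slot means,sds named numeric vectors (sensitivity, specificity,
#'   accuracy).
#' @slot selectedFold index of the selected fold.
#' @slot models list of trained models (possibly empty when only metrics
#'   were kept).
#' @export
setClass("CVResult",
  representation(perFold = "list", means = "numeric", sds = "numeric",
                 selectedFold = "integer", models = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@perFold) < 1L) msg <- c(msg, "need at least one fold")
    if (length(object@selectedFold) == 1L &&
        (object@selectedFold < 1L || object@selectedFold > length(object@perFold)))
      msg <- c(msg, "selectedFold out of range")
    if (is.null(msg)) TRUE else msg
  })

#' Saliency heatmap
#'
#' A non-negative class-activation map, resampled to the input-image extent
#' and min-max normalized: values lie in `[0, 1]` and the maximum is
#' exactly 1 unless the map is identically zero.
#'
#' @slot grid numeric matrix in `[0, 1]` with the input image's dimensions.
#' @slot method `"grad-cam"`, `"egrad-cam"` or `"ablation-cam"`.
#' @slot layer name of the audited convolutional layer.
#' @slot targetClass index of the explained class.
#' @export
setClass("SaliencyMap",
  representation(grid = "matrix", method = "character", layer = "character",
                 targetClass = "integer"),
  validity = function(object) {
    msg <- NULL
    g <- object@grid
    if (any(g < 0 | g > 1)) msg <- c(msg, "grid values must lie in [0, 1]")
    else if (max(g) > 0 && abs(max(g) - 1) > 1e-12)
      msg <- c(msg, "non-zero maps must attain max exactly 1")
    if (is.null(msg)) TRUE else msg
  })

#' Feature-map entropy audit
#'
#' Shannon entropies (bits) of every feature map at a convolutional layer,
#' and the percentage of maps whose entropy is exactly zero (constant maps
#' that cannot contribute to the decision).
#'
#' @slot entropies numeric vector of per-map entropies in bits.
#' @slot nZero number of zero-entropy maps.
#' @slot zeroEntropyRatio percentage `100 * nZero / length(entropies)`.
#' @slot layer audited layer name.
#' @export
setClass("FeatureAudit",
  representation(entropies = "numeric", nZero = "integer",
                 zeroEntropyRatio = "numeric", layer = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@zeroEntropyRatio < 0 || object@zeroEntropyRatio > 100)
      msg <- c(msg, "ratio must lie in [0, 100]")
    expect <- 100 * object@nZero / max(1L, length(object@entropies))
    if (abs(object@zeroEntropyRatio - expect) > 1e-9)
      msg <- c(msg, "ratio must equal 100 * nZero / total")
    if (is.null(msg)) TRUE else msg
  })

#' Named collection of lesion datasets
#'
#' Per-dataset benign/malignant counts with an optional file list and a
#' source tag; the integration point for pooling training collections.
#'
#' @slot datasets data.frame with columns `name`, `benign`, `malignant`,
#'   `source`.
#' @slot fileLists named list of character vectors (optional per-dataset
#'   file lists; when present, the length must equal the dataset total).
#' @export
setClass("DatasetManifest",
  representation(datasets = "data.frame", fileLists = "list"),
  validity = function(object) {
    msg <- NULL
    d <- object@datasets
    need <- c("name", "benign", "malignant")
    if (!all(need %in% names(d)))
      msg <- c(msg, "datasets needs columns name, benign, malignant")
    else {
      if (any(d$benign < 0) || any(d$malignant < 0))
        msg <- c(msg, "counts must be >= 0")
      if (anyDuplicated(d$name)) msg <- c(msg, "dataset names must be unique")
      for (nm in names(object@fileLists)) {
        i <- match(nm, d$name)
        if (is.na(i)) msg <- c(msg, sprintf("file list for unknown dataset '%s'", nm))
        else if (length(object@fileLists[[nm]]) != d$benign[i] + d$malignant[i])
          msg <- c(msg, sprintf("file list length mismatch for '%s'", nm))
      }
    }
    if (is.null(msg)) TRUE else msg
  })
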