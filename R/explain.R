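# Saliency maps and the zero-entropy feature-map audit.
#
# All three CAM variants weight the feature maps of a convolutional layer
# and display the rectified weighted sum, bilinearly upsampled to the
# input extent and min-max normalized.  Grad-CAM weights are spatial means
# of the class-logit gradient; EGrad-CAM additionally drops feature maps
# whose activation entropy is at or below a threshold (default: exactly
# zero, i.e. constant maps); Ablation-CAM weights are the relative logit
# drops when each map is zeroed and the forward pass re-run.  The class
# score is the pre-softmax logit.

#' Shannon entropy of a feature map
#'
#' Histogram entropy over `nBins` uniform bins spanning the map's own
#' `[min, max]` range, in bits.  A constant map returns exactly 0.
#'
#' @param map numeric matrix (or array) of activations.
#' @param nBins number of histogram bins (default 256).
#' @return entropy in bits.
#' @examples
#' featureEntropy(matrix(1, 4, 4))              # 0
#' featureEntropy(matrix(c(0, 1), 4, 4))        # 1
#' @export
featureEntropy <- function(map, nBins = 256L) {
  v <- as.vector(map)
  stopifnot(length(v) >= 1L)
  rng <- max(v) - min(v)
  if (rng == 0) return(0)
  bins <- pmin(floor((v - min(v)) / rng * nBins), nBins - 1L)
  p <- tabulate(bins + 1L, nbins = nBins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# index of a named layer; CAM targets must be convolutional
convLayerIndex <- function(model, layer) {
  nm <- vapply(model$spec@layers, `[[`, character(1), "name")
  i <- match(layer, nm)
  if (is.na(i)) stop(sprintf("no layer named '%s'", layer))
  if (model$spec@layers[[i]]$kind != "conv3x3")
    stop(sprintf("layer '%s' is not convolutional", layer))
  i
}

# inference forward pass from the output of layer `startIdx` to the logits
forwardTail <- function(net, startIdx, act) {
  layers <- net$spec@layers
  feat <- NULL
  for (i in (startIdx + 1L):length(layers)) {
    ly <- layers[[i]]; p <- net$params[[i]]
    if (ly$kind == "conv3x3") act <- convForward(act, p$W, p$b)$out
    else if (ly$kind == "batchnorm")
      act <- bnForward(act, p$gamma, p$beta, p$runMean, p$runVar,
                       training = FALSE)$out
    else if (ly$kind == "relu") act <- act * (act > 0)
    else if (ly$kind == "maxpool2x2") act <- maxpoolForward(act)$out
    else if (ly$kind == "gap") feat <- gapForward(act)$out
    else if (ly$kind == "fc")
      feat <- sweep(t(feat) %*% p$W, 2, p$b, "+")
    else if (ly$kind == "softmax") break
  }
  feat   # 1 x 2 logits
}

#' Activations and class-logit gradients at a convolutional layer
#'
#' Runs an inference-mode forward pass on one image and backpropagates
#' the chosen class's pre-softmax logit to the named convolutional
#' layer's output.
#'
#' @param model a trained `echonetModel`.
#' @param image grayscale matrix sized to the model input.
#' @param targetClass class index (1 = benign, 2 = malignant).
#' @param layer convolutional layer name (e.g. `"conv_6"`).
#' @return list with `activations` and `gradients` (both `(H, W, C, 1)`
#'   arrays) and the scalar `logit`.
#' @export
saliencyGradients <- function(model, image, targetClass, layer) {
  i <- convLayerIndex(model, layer)
  x <- imagesToArray(list(image))
  fw <- forwardPass(model, x, training = FALSE)
  dLogits <- matrix(0, 1, 2)
  dLogits[1, targetClass] <- 1
  bw <- backwardPass(model, fw$caches, dLogits, training = FALSE,
                     stopAtLayer = i)
  list(activations = fw$caches[[i]]$out, gradients = bw$dAct,
       logit = fw$logits[1, targetClass])
}

# bilinear (2-tap, centre-aligned, edge-clamped) resampling operator
bilinearOperator <- function(nIn, nOut) {
  W <- matrix(0, nOut, nIn)
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  i0 <- floor(src); t <- src - i0
  for (tap in 0:1) {
    idx <- clip(i0 + tap, 0, nIn - 1) + 1
    w <- if (tap == 0) 1 - t else t
    for (j in seq_len(nOut)) W[j, idx[j]] <- W[j, idx[j]] + w[j]
  }
  W
}

# weighted map sum -> rectify -> upsample -> normalize -> SaliencyMap
finishSaliency <- function(acts, weights, outDim, method, layer,
                           targetClass) {
  d <- dim(acts)
  cam <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) cam <- cam + weights[k] * acts[, , k, 1]
  cam <- pmax(cam, 0)
  up <- bilinearOperator(d[1], outDim[1]) %*% cam %*%
    t(bilinearOperator(d[2], outDim[2]))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  methods::new("SaliencyMap", grid = up, method = method, layer = layer,
               targetClass = as.integer(targetClass))
}

#' Grad-CAM saliency map
#'
#' Per-map weights are the spatial means of the class-logit gradient at
#' the target convolutional layer; the heatmap is the rectified weighted
#' sum of the feature maps, bilinearly upsampled to the image extent and
#' min-max normalized.
#'
#' @inheritParams saliencyGradients
#' @return a [SaliencyMap-class].
#' @export
gradCAM <- function(model, image, targetClass, layer) {
  sg <- saliencyGradients(model, image, targetClass, layer)
  weights <- apply(sg$gradients, 3, mean)
  finishSaliency(sg$activations, weights, dim(image), "grad-cam", layer,
                 targetClass)
}

#' Entropy-gated Grad-CAM (EGrad-CAM)
#'
#' Identical to [gradCAM()] except that feature maps whose histogram
#' entropy is at or below `entropyThreshold` (default 0: constant maps)
#' are excluded from the weighted sum.  If every map is excluded, a zero
#' map is returned with a warning.
#'
#' @inheritParams saliencyGradients
#' @param entropyThreshold entropy cut in bits (default 0).
#' @param nBins histogram bins for [featureEntropy()].
#' @return a [SaliencyMap-class].
#' @export
egradCAM <- function(model, image, targetClass, layer,
                     entropyThreshold = 0, nBins = 256L) {
  sg <- saliencyGradients(model, image, targetClass, layer)
  weights <- apply(sg$gradients, 3, mean)
  ent <- apply(sg$activations, 3, featureEntropy, nBins = nBins)
  keep <- ent > entropyThreshold
  if (!any(keep)) {
    warning("all feature maps excluded by the entropy threshold; zero map")
    weights[] <- 0
  } else weights[!keep] <- 0
  finishSaliency(sg$activations, weights, dim(image), "egrad-cam", layer,
                 targetClass)
}

#' Ablation-CAM saliency map
#'
#' Each feature map's weight is its relative contribution to the class
#' logit, `(y_c - y_c^{map k zeroed}) / y_c`, measured by literally
#' re-running the forward pass from the target layer with that map set to
#' zero.  Requires `y_c != 0`.
#'
#' @inheritParams saliencyGradients
#' @return a [SaliencyMap-class].
#' @export
ablationCAM <- function(model, image, targetClass, layer) {
  i <- convLayerIndex(model, layer)
  x <- imagesToArray(list(image))
  fw <- forwardPass(model, x, training = FALSE)
  acts <- fw$caches[[i]]$out
  yc <- fw$logits[1, targetClass]
  if (yc == 0) stop("class logit is zero; ablation weights are undefined")
  nMaps <- dim(acts)[3]
  weights <- numeric(nMaps)
  for (k in seq_len(nMaps)) {
    ablated <- acts
    ablated[, , k, ] <- 0
    yk <- forwardTail(model, i, ablated)[1, targetClass]
    weights[k] <- (yc - yk) / yc
  }
  finishSaliency(acts, weights, dim(image), "ablation-cam", layer,
                 targetClass)
}

#' Zero-entropy feature-map audit
#'
#' Computes the histogram entropy of every feature map at a convolutional
#' layer for one image and reports the percentage of maps with entropy
#' exactly zero - constant maps that cannot contribute to the
#' classification decision.
#'
#' @param model a trained `echonetModel`.
#' @param image grayscale input matrix.
#' @param layer convolutional layer name.
#' @param nBins histogram bins.
#' @return a [FeatureAudit-class].
#' @export
zeroEntropyRatio <- function(model, image, layer, nBins = 256L) {
  i <- convLayerIndex(model, layer)
  x <- imagesToArray(list(image))
  acts <- forwardPass(model, x, training = FALSE)$caches[[i]]$out
  ent <- apply(acts, 3, featureEntropy, nBins = nBins)
  nz <- sum(ent == 0)
  methods::new("FeatureAudit", entropies = ent, nZero = as.integer(nz),
               zeroEntropyRatio = 100 * nz / length(ent), layer = layer)
}

#' Per-map audit table
#'
#' @param audit a [FeatureAudit-class].
#' @return data.frame with `map_index`, `entropy_bits`, `zero` columns,
#'   ready for CSV export.
#' @export
auditTable <- function(audit) {
  data.frame(map_index = seq_along(audit@entropies),
             entropy_bits = audit@entropies,
             zero = audit@entropies == 0)
}
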