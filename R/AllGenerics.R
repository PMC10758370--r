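# Generics and accessors.  Slot access from user code goes through these.

#' @name accessors
#' @title Accessor generics
#' @description Read-only accessors for the package's S4 containers.
#' @param x an echonet object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("boundaryPoints", function(x) standardGeneric("boundaryPoints"))
#' @rdname accessors
#' @export
setGeneric("lesionLabel", function(x) standardGeneric("lesionLabel"))
#' @rdname accessors
#' @export
setGeneric("nConvLayers", function(x) standardGeneric("nConvLayers"))
#' @rdname accessors
#' @export
setGeneric("finalBlockKernels", function(x) standardGeneric("finalBlockKernels"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("bestObservation", function(x) standardGeneric("bestObservation"))
#' @rdname accessors
#' @export
setGeneric("bestSoFar", function(x) standardGeneric("bestSoFar"))
#' @rdname accessors
#' @export
setGeneric("entropies", function(x) standardGeneric("entropies"))
#' @rdname accessors
#' @export
setGeneric("zeroEntropyPercent", function(x) standardGeneric("zeroEntropyPercent"))
#' @rdname accessors
#' @export
setGeneric("saliencyGrid", function(x) standardGeneric("saliencyGrid"))

#' @rdname accessors
#' @export
setMethod("pixels", "AnnotatedImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("boundaryPoints", "AnnotatedImage", function(x) x@boundaryPoints)
#' @rdname accessors
#' @export
setMethod("lesionLabel", "AnnotatedImage", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("nConvLayers", "ArchitectureSpec", function(x) x@nConvLayers)
#' @rdname accessors
#' @export
setMethod("finalBlockKernels", "ArchitectureSpec", function(x) x@finalBlockKernels)
#' @rdname accessors
#' @export
setMethod("nParameters", "ArchitectureSpec", function(x) x@nParameters)
#' @rdname accessors
#' @export
setMethod("layerNames", "ArchitectureSpec",
          function(x) vapply(x@layers, `[[`, character(1), "name"))
#' @rdname accessors
#' @export
setMethod("sensitivity", "Metrics", function(x) x@sensitivity)
#' @rdname accessors
#' @export
setMethod("specificity", "Metrics", function(x) x@specificity)
#' @rdname accessors
#' @export
setMethod("accuracy", "Metrics", function(x) x@accuracy)
#' @rdname accessors
#' @export
setMethod("observations", "SearchHistory", function(x) x@observations)
#' @rdname accessors
#' @export
setMethod("bestObservation", "SearchHistory",
          function(x) x@observations[[x@bestIndex]])
#' @rdname accessors
#' @export
setMethod("bestSoFar", "SearchHistory", function(x) x@bestSoFar)
#' @rdname accessors
#' @export
setMethod("entropies", "FeatureAudit", function(x) x@entropies)
#' @rdname accessors
#' @export
setMethod("zeroEntropyPercent", "FeatureAudit", function(x) x@zeroEntropyRatio)
#' @rdname accessors
#' @export
setMethod("saliencyGrid", "SaliencyMap", function(x) x@grid)

# ---- show methods -------------------------------------------------------

setMethod("show", "Rect", function(object) {
  cat(sprintf("Rect [%d, %d) x [%d, %d)  (w=%d, h=%d)\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              object@xMax - object@xMin, object@yMax - object@yMin))
})

setMethod("show", "LesionSpec", function(object) {
  cat(sprintf("LesionSpec: %s, %dpx, center=(%.1f, %.1f), radii=(%.1f, %.1f)\n",
              object@label, object@imageSize,
              object@center[1], object@center[2],
              object@radii[1], object@radii[2]))
  cat(sprintf("  irregularity=%.3f, interior=%.2f, background=%.2f\n",
              object@irregularity, object@interiorLevel, object@backgroundLevel))
  cat(sprintf("  posterior=%s(%.2f), speckle=%.2f\n",
              object@posteriorEffect, object@posteriorStrength,
              object@speckleStrength))
})

setMethod("show", "AnnotatedImage", function(object) {
  cat(sprintf("AnnotatedImage: %dx%d %s lesion, %d boundary points, seed=%d\n",
              nrow(object@pixels), ncol(object@pixels), object@label,
              nrow(object@boundaryPoints), object@seed))
})

setMethod("show", "HyperParams", function(object) {
  cat(sprintf("HyperParams: B=%d, Opt=%s, Lr=%.4g, Mn=%d, Epo=%d\n",
              object@B, object@Opt, object@Lr, object@Mn, object@Epo))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: input %dx%dx%d, B=%d\n",
              object@inputSize, object@inputSize, object@channels, object@B))
  cat(sprintf("  %d conv layers in 3 blocks (%d/%d/%d kernels), %s parameters\n",
              object@nConvLayers, object@baseKernels, 2L * object@baseKernels,
              4L * object@baseKernels,
              format(object@nParameters, big.mark = ",")))
})

setMethod("show", "SearchHistory", function(object) {
  n <- length(object@observations)
  cat(sprintf("SearchHistory: %d evaluations, seed=%d\n", n, object@seed))
  if (n > 0L) {
    best <- object@observations[[object@bestIndex]]
    cat(sprintf("  best error %.4f at iteration %d: ", best$error,
                object@bestIndex))
    show(best$hp)
  }
})

setMethod("show", "Metrics", function(object) {
  cat(sprintf("Metrics: TP=%d FP=%d TN=%d FN=%d\n",
              object@TP, object@FP, object@TN, object@FN))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%\n",
              object@sensitivity, object@specificity, object@accuracy))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult over %d folds (selected fold %d)\n",
              length(object@perFold), object@selectedFold))
  cat(sprintf("  mean (sd): sensitivity %.2f%% (%.2f), specificity %.2f%% (%.2f), accuracy %.2f%% (%.2f)\n",
              object@means["sensitivity"], object@sds["sensitivity"],
              object@means["specificity"], object@sds["specificity"],
              object@means["accuracy"], object@sds["accuracy"]))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (%s) for class %d at layer '%s': %dx%d, max=%.3f\n",
              object@method, object@targetClass, object@layer,
              nrow(object@grid), ncol(object@grid), max(object@grid)))
})

setMethod("show", "FeatureAudit", function(object) {
  cat(sprintf("FeatureAudit at '%s': %d maps, %d with zero entropy (%.2f%%)\n",
              object@layer, length(object@entropies), object@nZero,
              object@zeroEntropyRatio))
})

setMethod("show", "DatasetManifest", function(object) {
  d <- object@datasets
  cat(sprintf("DatasetManifest: %d datasets, %d images (%d benign, %d malignant)\n",
              nrow(d), sum(d$benign) + sum(d$malignant),
              sum(d$benign), sum(d$malignant)))
})
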