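# Data augmentation: vertical-axis mirroring and truncated-SVD
# compression at fixed retained-fraction ratios.  Each RoI yields exactly
# four additional images (mirror, svd@0.25, svd@0.35, svd@0.45), a 5x
# training pool.  SVD compression preserves the gross lesion geometry
# while attenuating fine texture; reconstructions are clipped to [0, 1]
# rather than renormalized so intensity calibration survives.

#' Augmentation bundle for one RoI image
#'
#' @slot original the source grayscale matrix.
#' @slot augmented list of 4 matrices in fixed order.
#' @slot provenance operator tags, `c("mirror", "svd@0.25", "svd@0.35",
#'   "svd@0.45")`.
#' @export
setClass("AugmentationSet",
  representation(original = "matrix", augmented = "list",
                 provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@augmented) != 4L)
      msg <- c(msg, "exactly 4 augmented images required")
    dims <- vapply(object@augmented, function(m) all(dim(m) == dim(object@original)),
                   logical(1))
    if (!all(dims)) msg <- c(msg, "augmented images must match the original's dimensions")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "AugmentationSet", function(object) {
  cat(sprintf("AugmentationSet: %dx%d original + %d augmented (%s)\n",
              nrow(object@original), ncol(object@original),
              length(object@augmented),
              paste(object@provenance, collapse = ", ")))
})

#' Mirror an image across its vertical axis
#'
#' Reverses the column order; rows are untouched.  An involution:
#' `mirrorImage(mirrorImage(x))` is `x` exactly.
#'
#' @param image numeric matrix.
#' @return the mirrored matrix.
#' @export
mirrorImage <- function(image) {
  stopifnot(isImageMatrix(image))
  image[, ncol(image):1, drop = FALSE]
}

#' Compress an image by truncated SVD
#'
#' Keeps the top `k = max(1, round(ratio * min(h, w)))` singular triplets
#' (rounding half away from zero) and reconstructs; the result is clipped
#' to `[0, 1]`.  By the Eckart-Young theorem the pre-clipping Frobenius
#' reconstruction error equals `sqrt(sum of the discarded squared singular
#' values)` and is non-increasing in `ratio`.
#'
#' @param image numeric matrix, at least 2x2.
#' @param ratio fraction of singular values to retain, in `(0, 1]`.
#' @return the compressed matrix, same dimensions, clipped to `[0, 1]`.
#' @export
svdCompress <- function(image, ratio) {
  stopifnot(isImageMatrix(image), nrow(image) >= 2L, ncol(image) >= 2L)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("'ratio' must lie in (0, 1]")
  k <- max(1L, as.integer(roundHalfAway(ratio * min(dim(image)))))
  s <- svd(image, nu = k, nv = k)
  rec <- s$u %*% (s$d[seq_len(k)] * t(s$v))
  clip(rec)
}

#' Generate the fixed augmentation set for one RoI
#'
#' Produces exactly four additional images in the fixed order: mirror,
#' then SVD compression retaining 25%, 35% and 45% of the singular values.
#'
#' @param image RoI grayscale matrix.
#' @param svdRatios retained-fraction ratios (default `c(0.25, 0.35,
#'   0.45)`).
#' @return an [AugmentationSet-class].
#' @examples
#' set <- augmentRoi(matrix(runif(64), 8, 8))
#' set
#' @export
augmentRoi <- function(image, svdRatios = c(0.25, 0.35, 0.45)) {
  stopifnot(isImageMatrix(image))
  aug <- c(list(mirrorImage(image)),
           lapply(svdRatios, function(r) svdCompress(image, r)))
  methods::new("AugmentationSet",
    original = image, augmented = aug,
    provenance = c("mirror", sprintf("svd@%.2f", svdRatios)))
}
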