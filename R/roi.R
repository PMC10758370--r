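# Region-of-interest extraction.
#
# Boundary-point annotations become an axis-aligned bounding rectangle,
# which is grown by a margin fraction (default 8%, split half per side) to
# keep the surrounding-tissue contrast, then cropped and resampled with
# bicubic (Catmull-Rom, a = -0.5) interpolation to the network input size.
# All rectangles are 0-based and half-open.

#' Construct a rectangle
#'
#' @param xMin,yMin,xMax,yMax 0-based half-open pixel bounds
#'   (`xMin < xMax`, `yMin < yMax`).
#' @return a [Rect-class].
#' @export
rect <- function(xMin, yMin, xMax, yMax) {
  methods::new("Rect", xMin = as.integer(xMin), yMin = as.integer(yMin),
               xMax = as.integer(xMax), yMax = as.integer(yMax))
}

#' Width and height of a rectangle
#' @param r a [Rect-class].
#' @return integer width / height.
#' @export
rectWidth <- function(r) r@xMax - r@xMin

#' @rdname rectWidth
#' @export
rectHeight <- function(r) r@yMax - r@yMin

rectInside <- function(inner, outer) {
  inner@xMin >= outer@xMin && inner@yMin >= outer@yMin &&
    inner@xMax <= outer@xMax && inner@yMax <= outer@yMax
}

#' Axis-aligned bounding rectangle of annotation points
#'
#' The smallest half-open rectangle containing every point: per axis
#' `[floor(min), floor(max) + 1)`.  At least three non-collinear points are
#' required; a degenerate (zero-area) point set is rejected.
#'
#' @param points numeric matrix with columns `x`, `y` (0-based pixels).
#' @return a [Rect-class].
#' @examples
#' boundingRect(cbind(c(10, 30, 10, 30), c(20, 20, 60, 60)))
#' @export
boundingRect <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("'points' must be a two-column matrix (x, y)")
  if (nrow(points) < 3L)
    stop("need at least 3 annotation points")
  # collinearity: every point lies on the line through the first two
  # distinct points -> zero-area spread
  v1 <- points[2, ] - points[1, ]
  cross <- (points[, 1] - points[1, 1]) * v1[2] -
           (points[, 2] - points[1, 2]) * v1[1]
  if (all(abs(cross) < 1e-9))
    stop("annotation points are collinear (zero-area spread)")
  rect(floor(min(points[, 1])), floor(min(points[, 2])),
       floor(max(points[, 1])) + 1L, floor(max(points[, 2])) + 1L)
}

#' Expand a rectangle by a margin fraction
#'
#' Width and height each grow by `fraction` in total (half added on each
#' side), rounded outward to whole pixels and clamped to the image extent.
#' The result always contains the input rectangle, and growth is monotone
#' in `fraction`.
#'
#' @param r a [Rect-class] inside `imageExtent`.
#' @param fraction margin fraction in `[0, 1)`; the default 0.08 adds
#'   approximately 8% of the width and height.
#' @param imageExtent a [Rect-class] giving the full image bounds.
#' @return the expanded, clamped [Rect-class].
#' @examples
#' expandRect(rect(50, 50, 150, 100), 0.08, rect(0, 0, 400, 400))
#' @export
expandRect <- function(r, fraction = 0.08, imageExtent) {
  stopifnot(methods::is(r, "Rect"), methods::is(imageExtent, "Rect"))
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must lie in [0, 1)")
  if (!rectInside(r, imageExtent))
    stop("rectangle lies outside the image extent")
  hw <- rectWidth(r) * fraction / 2
  hh <- rectHeight(r) * fraction / 2
  rect(max(imageExtent@xMin, floor(r@xMin - hw)),
       max(imageExtent@yMin, floor(r@yMin - hh)),
       min(imageExtent@xMax, ceiling(r@xMax + hw)),
       min(imageExtent@yMax, ceiling(r@yMax + hh)))
}

# Catmull-Rom (a = -0.5) weights for fractional offset t in [0, 1),
# applied to samples at positions i0-1, i0, i0+1, i0+2
catmullRomWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((-t3 + 2 * t2 - t) / 2,
        (3 * t3 - 5 * t2 + 2) / 2,
        (-3 * t3 + 4 * t2 + t) / 2,
        (t3 - t2) / 2)
}

# dense (nOut x nIn) resampling operator along one axis; edge samples are
# clamped (replicated), pixel centres aligned between grids
resampleOperator <- function(nIn, nOut) {
  W <- matrix(0, nOut, nIn)
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5   # 0-based source coords
  i0 <- floor(src)
  wts <- catmullRomWeights(src - i0)
  for (tap in 0:3) {
    idx <- clip(i0 - 1 + tap, 0, nIn - 1) + 1
    for (j in seq_len(nOut)) W[j, idx[j]] <- W[j, idx[j]] + wts[j, tap + 1]
  }
  W
}

#' Crop a rectangle and resample to a target size
#'
#' Extracts `rect` from the image and resizes it to `target` width/height
#' with separable bicubic (Catmull-Rom, a = -0.5) interpolation.  Output
#' values are clipped to the intensity range of the cropped region, so no
#' interpolation overshoot leaves the input range.
#'
#' @param image numeric matrix in `[0, 1]` (rows = y).
#' @param r a [Rect-class] inside the image.
#' @param target integer `(width, height)` of the output, each >= 8.
#' @return numeric `target[2] x target[1]` matrix.
#' @export
cropResize <- function(image, r, target = c(128L, 128L)) {
  stopifnot(isImageMatrix(image), methods::is(r, "Rect"))
  extent <- rect(0L, 0L, ncol(image), nrow(image))
  if (!rectInside(r, extent))
    stop("rectangle lies outside the image")
  if (any(target < 8L))
    stop("target size must be at least 8x8")
  crop <- image[(r@yMin + 1L):r@yMax, (r@xMin + 1L):r@xMax, drop = FALSE]
  out <- resampleOperator(nrow(crop), target[2]) %*% crop %*%
    t(resampleOperator(ncol(crop), target[1]))
  clip(out, min(crop), max(crop))
}

#' Full RoI extraction for an annotated image
#'
#' Convenience wrapper: bounding rectangle of the annotation, margin
#' expansion, bicubic crop-resize.
#'
#' @param img an [AnnotatedImage-class].
#' @param fraction margin fraction (default 0.08).
#' @param target output `(width, height)`.
#' @return list with the resized RoI matrix (`roi`), the expanded source
#'   rectangle (`rect`) and the label.
#' @export
extractRoi <- function(img, fraction = 0.08, target = c(128L, 128L)) {
  px <- pixels(img)
  extent <- rect(0L, 0L, ncol(px), nrow(px))
  r <- expandRect(boundingRect(boundaryPoints(img)), fraction, extent)
  list(roi = cropResize(px, r, target), rect = r, label = lesionLabel(img))
}
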