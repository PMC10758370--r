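# Synthetic ultrasound-like lesion images.
#
# The generator emulates the gross appearance of B-mode breast lesions:
# a darker (hypo-/anechoic) roughly elliptical lesion on a brighter
# speckled background, with a class-dependent boundary irregularity and a
# posterior column band that is brightened (enhancement, typical of cysts)
# or darkened (shadowing, typical of invasive masses).  Speckle is the
# standard first-order multiplicative model: pixel = clean * noise with
# unit-mean gamma noise.

#' Irregularity threshold separating benign from malignant specs
#'
#' Benign synthetic lesions keep the relative amplitude of their radial
#' boundary perturbation below this value; malignant lesions lie above it.
#' The value 0.08 leaves a visible margin between the default class
#' distributions while keeping malignant contours smooth enough to remain
#' lesion-like.
#'
#' @return the threshold (dimensionless), 0.08.
#' @export
irregularityThreshold <- function() 0.08

#' Construct a lesion specification
#'
#' @param label `"benign"` or `"malignant"`.
#' @param imageSize square image side in pixels (>= 64).  The default 160
#'   leaves room for a 128x128 region of interest after margin expansion.
#' @param center lesion centre `(x, y)` in 0-based pixel coordinates.
#' @param radii ellipse radii `(rx, ry)` in pixels.
#' @param irregularity amplitude of the radial boundary perturbation,
#'   relative to the local ellipse radius.  Must respect the class
#'   threshold of [irregularityThreshold()].
#' @param interiorLevel,backgroundLevel relative intensities in `[0, 1]`,
#'   `interiorLevel < backgroundLevel`.
#' @param posteriorEffect `"enhancement"`, `"shadowing"` or `"none"`.
#' @param posteriorStrength multiplicative strength of the posterior
#'   effect in `[0, 1]`.
#' @param speckleStrength standard deviation of the unit-mean
#'   multiplicative speckle field (0 disables speckle).
#' @return a [LesionSpec-class].
#' @examples
#' sp <- lesionSpec("benign", irregularity = 0.03)
#' sp
#' @export
lesionSpec <- function(label,
                       imageSize = 160L,
                       center = c(imageSize / 2, imageSize / 2),
                       radii = c(0.22, 0.17) * imageSize,
                       irregularity = if (label == "benign") 0.03 else 0.18,
                       interiorLevel = 0.15,
                       backgroundLevel = 0.55,
                       posteriorEffect = "none",
                       posteriorStrength = 0.3,
                       speckleStrength = 0.25) {
  methods::new("LesionSpec",
    label = label, imageSize = as.integer(imageSize),
    center = as.numeric(center), radii = as.numeric(radii),
    irregularity = as.numeric(irregularity),
    interiorLevel = as.numeric(interiorLevel),
    backgroundLevel = as.numeric(backgroundLevel),
    posteriorEffect = posteriorEffect,
    posteriorStrength = as.numeric(posteriorStrength),
    speckleStrength = as.numeric(speckleStrength))
}

# Low-order sinusoid mixture used to perturb the contour radius.  The
# coefficients are drawn once per image from the seeded stream and
# normalized so the mixture stays within [-1, 1]; harmonics 2..5 keep the
# contour smooth but clearly non-elliptical at malignant amplitudes.
radialPerturbation <- function() {
  m <- 2:5
  a <- stats::runif(length(m), 0.3, 1)
  a <- a / sum(a)
  phi <- stats::runif(length(m), 0, 2 * pi)
  function(theta) {
    s <- 0
    for (j in seq_along(m)) s <- s + a[j] * sin(m[j] * theta + phi[j])
    s
  }
}

#' Generate one annotated synthetic lesion image
#'
#' Renders the two-level lesion/background image described by `spec`,
#' applies the posterior column effect below the lesion, multiplies in the
#' speckle field and samples ordered boundary points on the perturbed
#' contour.  The result is fully determined by `(spec, seed)`.
#'
#' @param spec a [LesionSpec-class].
#' @param seed integer seed; the same `(spec, seed)` pair always yields an
#'   identical image and annotation.
#' @param nBoundaryPoints number of ordered contour points to annotate
#'   (>= 8).
#' @return an [AnnotatedImage-class].
#' @examples
#' img <- generateLesionImage(lesionSpec("malignant"), seed = 7)
#' img
#' @export
generateLesionImage <- function(spec, seed, nBoundaryPoints = 24L) {
  methods::validObject(spec)
  stopifnot(nBoundaryPoints >= 8L)
  n <- spec@imageSize
  withSeed(seed, {
    perturb <- radialPerturbation()

    # pixel-centre coordinate grids, 0-based; rows are y, columns are x
    xs <- matrix(rep(0:(n - 1L), each = n), nrow = n)   # column index
    ys <- matrix(rep(0:(n - 1L), times = n), nrow = n)  # row index
    dx <- (xs - spec@center[1]) / spec@radii[1]
    dy <- (ys - spec@center[2]) / spec@radii[2]
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(ys - spec@center[2], xs - spec@center[1])
    inside <- rho < 1 + spec@irregularity * perturb(theta)

    clean <- matrix(spec@backgroundLevel, n, n)
    clean[inside] <- spec@interiorLevel

    # posterior enhancement/shadowing: multiplicative gain on the column
    # band spanned by the lesion, for all rows below its lowest point
    if (spec@posteriorEffect != "none" && any(inside)) {
      rowsIn <- which(apply(inside, 1, any))
      colsIn <- which(apply(inside, 2, any))
      lastRow <- max(rowsIn)
      if (lastRow < n) {
        gain <- if (spec@posteriorEffect == "enhancement")
          1 + spec@posteriorStrength else 1 - spec@posteriorStrength
        band <- clean[(lastRow + 1L):n, colsIn, drop = FALSE]
        clean[(lastRow + 1L):n, colsIn] <- clip(band * gain)
      }
    }

    px <- if (spec@speckleStrength > 0) {
      shape <- 1 / spec@speckleStrength^2
      noise <- matrix(stats::rgamma(n * n, shape = shape, rate = shape), n, n)
      clip(clean * noise)
    } else clean

    thetaPts <- 2 * pi * (seq_len(nBoundaryPoints) - 1L) / nBoundaryPoints
    r <- 1 + spec@irregularity * perturb(thetaPts)
    bp <- cbind(x = spec@center[1] + spec@radii[1] * r * cos(thetaPts),
                y = spec@center[2] + spec@radii[2] * r * sin(thetaPts))

    methods::new("AnnotatedImage",
      pixels = px, boundaryPoints = bp, label = spec@label,
      seed = as.integer(seed),
      spec = specToList(spec))
  })
}

# serializable view of a LesionSpec (kept on the AnnotatedImage and in the
# JSON sidecar)
specToList <- function(spec) {
  list(label = spec@label, imageSize = spec@imageSize,
       center = spec@center, radii = spec@radii,
       irregularity = spec@irregularity,
       interiorLevel = spec@interiorLevel,
       backgroundLevel = spec@backgroundLevel,
       posteriorEffect = spec@posteriorEffect,
       posteriorStrength = spec@posteriorStrength,
       speckleStrength = spec@speckleStrength)
}

listToSpec <- function(lst) {
  methods::new("LesionSpec",
    label = lst$label, imageSize = as.integer(lst$imageSize),
    center = as.numeric(lst$center), radii = as.numeric(lst$radii),
    irregularity = as.numeric(lst$irregularity),
    interiorLevel = as.numeric(lst$interiorLevel),
    backgroundLevel = as.numeric(lst$backgroundLevel),
    posteriorEffect = lst$posteriorEffect,
    posteriorStrength = as.numeric(lst$posteriorStrength),
    speckleStrength = as.numeric(lst$speckleStrength))
}

# Draw one class-conditional LesionSpec from the generator's default study
# conditions.  Called inside a seeded stream.
sampleLesionSpec <- function(label, imageSize) {
  benign <- label == "benign"
  center <- imageSize / 2 + stats::runif(2, -8, 8)
  radii <- c(stats::runif(1, 0.15, 0.26), stats::runif(1, 0.12, 0.20)) * imageSize
  irr <- if (benign) stats::runif(1, 0.01, 0.05) else stats::runif(1, 0.12, 0.28)
  interior <- if (benign) stats::runif(1, 0.08, 0.18) else stats::runif(1, 0.20, 0.32)
  post <- if (stats::runif(1) < 0.7) {
    if (benign) "enhancement" else "shadowing"
  } else "none"
  lesionSpec(label, imageSize = imageSize, center = center, radii = radii,
             irregularity = irr, interiorLevel = interior,
             backgroundLevel = stats::runif(1, 0.45, 0.60),
             posteriorEffect = post,
             posteriorStrength = stats::runif(1, 0.2, 0.5),
             speckleStrength = 0.25)
}

#' Generate a labelled synthetic dataset
#'
#' Draws per-image lesion specifications from class-conditional
#' distributions (benign: near-elliptical, anechoic, mostly posterior
#' enhancement; malignant: irregular contour, hypoechoic, mostly posterior
#' shadowing) and renders each with a seed derived from the master seed.
#'
#' @param nBenign,nMalignant per-class image counts (>= 0).
#' @param seed master integer seed; per-image seeds are derived from it.
#' @param imageSize square image side in pixels.
#' @return a list of [AnnotatedImage-class], benign images first.
#' @examples
#' ds <- generateDataset(2, 2, seed = 1, imageSize = 64)
#' table(vapply(ds, lesionLabel, character(1)))
#' @export
generateDataset <- function(nBenign, nMalignant, seed, imageSize = 160L) {
  if (nBenign < 0 || nMalignant < 0)
    stop("class counts must be non-negative")
  labels <- c(rep("benign", nBenign), rep("malignant", nMalignant))
  lapply(seq_along(labels), function(i) {
    si <- deriveSeed(seed, i)
    spec <- withSeed(si, sampleLesionSpec(labels[i], imageSize))
    generateLesionImage(spec, seed = deriveSeed(si, 1L))
  })
}

#' Boundary roughness statistic
#'
#' Compactness of the annotated contour polygon: `P^2 / (4 pi A)` with
#' perimeter `P` and shoelace area `A`.  Equals 1 for a circle and grows
#' with boundary irregularity; used to verify that the synthetic classes
#' carry a shape signal.
#'
#' @param points numeric matrix of ordered contour points, columns `x`, `y`.
#' @return roughness (dimensionless, >= 1 up to discretisation).
#' @export
boundaryRoughness <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 3L)
  nxt <- c(2:nrow(points), 1L)
  dx <- points[nxt, 1] - points[, 1]
  dy <- points[nxt, 2] - points[, 2]
  perim <- sum(sqrt(dx^2 + dy^2))
  area <- abs(sum(points[, 1] * points[nxt, 2] -
                  points[nxt, 1] * points[, 2])) / 2
  perim^2 / (4 * pi * area)
}
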