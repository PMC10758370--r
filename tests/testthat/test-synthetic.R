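# Synthetic lesion-image generator.

test_that("zero-noise, zero-irregularity spec gives an exact two-level ellipse", {
  sp <- lesionSpec("benign", speckleStrength = 0, irregularity = 0,
                   posteriorEffect = "none")
  img <- generateLesionImage(sp, seed = 1)
  px <- pixels(img)
  expect_setequal(unique(as.vector(px)), c(sp@interiorLevel, sp@backgroundLevel))
  # interior pixels are exactly interiorLevel inside the ellipse mask
  n <- sp@imageSize
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  inside <- ((xs - sp@center[1]) / sp@radii[1])^2 +
            ((ys - sp@center[2]) / sp@radii[2])^2 < 1
  expect_true(all(px[inside] == sp@interiorLevel))
  expect_true(all(px[!inside] == sp@backgroundLevel))
})

test_that("generation is deterministic for a fixed (spec, seed)", {
  sp <- lesionSpec("malignant", speckleStrength = 0.3)
  a <- generateLesionImage(sp, seed = 7)
  b <- generateLesionImage(sp, seed = 7)
  expect_identical(pixels(a), pixels(b))
  expect_identical(boundaryPoints(a), boundaryPoints(b))
  c <- generateLesionImage(sp, seed = 8)
  expect_false(identical(pixels(a), pixels(c)))
})

test_that("lesion interior is darker than background in every generated image", {
  ds <- generateDataset(50, 50, seed = 11, imageSize = 64)
  for (img in ds) {
    px <- pixels(img)
    bp <- boundaryPoints(img)
    # brute-force mask from the annotated contour polygon (even-odd rule)
    n <- nrow(px)
    inside <- matrix(FALSE, n, n)
    for (row in seq_len(n)) {
      y <- row - 1
      xs <- c()
      m <- nrow(bp)
      for (j in seq_len(m)) {
        p1 <- bp[j, ]; p2 <- bp[j %% m + 1, ]
        if ((p1[2] > y) != (p2[2] > y)) {
          xs <- c(xs, p1[1] + (y - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2]))
        }
      }
      if (length(xs) >= 2) {
        xs <- sort(xs)
        for (k in seq(1, length(xs) - 1, by = 2)) {
          cols <- which(0:(n - 1) > xs[k] & 0:(n - 1) < xs[k + 1])
          inside[row, cols] <- TRUE
        }
      }
    }
    if (sum(inside) > 10 && sum(!inside) > 10)
      expect_lt(mean(px[inside]), mean(px[!inside]))
  }
})

test_that("posterior effects brighten or darken the band below the lesion", {
  base <- list(speckleStrength = 0, irregularity = 0, posteriorStrength = 0.4)
  mk <- function(eff) do.call(lesionSpec,
    c(list(label = "benign", posteriorEffect = eff), base))
  none <- pixels(generateLesionImage(mk("none"), 1))
  enh <- pixels(generateLesionImage(mk("enhancement"), 1))
  sha <- pixels(generateLesionImage(mk("shadowing"), 1))
  band <- none != enh | none != sha
  expect_true(any(band))
  expect_true(all(enh[band] >= none[band]))
  expect_true(all(sha[band] <= none[band]))
  # band sits strictly below the lesion's lowest row
  lesionRows <- which(apply(none == mk("none")@interiorLevel, 1, any))
  expect_gt(min(which(apply(band, 1, any))), max(lesionRows))
})

test_that("dataset generation conserves per-class counts and seeds", {
  ds <- generateDataset(10, 10, seed = 1)
  expect_length(ds, 20)
  labs <- vapply(ds, lesionLabel, character(1))
  expect_equal(sum(labs == "benign"), 10)
  expect_equal(sum(labs == "malignant"), 10)

  onlyMal <- generateDataset(0, 5, seed = 1)
  expect_length(onlyMal, 5)
  expect_true(all(vapply(onlyMal, lesionLabel, character(1)) == "malignant"))

  expect_error(generateDataset(-1, 5, seed = 1), "non-negative")

  again <- generateDataset(10, 10, seed = 1)
  expect_identical(lapply(ds, pixels), lapply(again, pixels))
})

test_that("boundary roughness separates the classes (rank test)", {
  d <- tinyDataset()
  rough <- vapply(d$images, function(im) boundaryRoughness(boundaryPoints(im)),
                  numeric(1))
  ben <- rough[d$labels == "benign"]
  mal <- rough[d$labels == "malignant"]
  expect_lt(wilcox.test(ben, mal)$p.value, 0.01)
  expect_lt(median(ben), median(mal))
})

test_that("simple intensity/shape features make the classes linearly separable", {
  ds <- generateDataset(100, 100, seed = 3, imageSize = 64)
  feats <- t(vapply(ds, function(im) {
    roi <- extractRoi(im, 0.08, c(16, 16))$roi
    c(mean(roi), boundaryRoughness(boundaryPoints(im)))
  }, numeric(2)))
  y <- as.integer(vapply(ds, lesionLabel, character(1)) == "malignant")
  fit <- suppressWarnings(glm(y ~ feats[, 1] + feats[, 2], family = binomial))
  acc <- mean((fitted(fit) > 0.5) == y)
  expect_gte(acc, 0.9)
})

test_that("spec invariants reject malformed lesions", {
  expect_error(lesionSpec("benign", irregularity = 0.2), "irregularity")
  expect_error(lesionSpec("malignant", irregularity = 0.01), "irregularity")
  expect_error(lesionSpec("benign", interiorLevel = 0.7,
                          backgroundLevel = 0.5), "hypoechoic")
  # lesion poking outside the image is rejected with a clear message
  expect_error(lesionSpec("benign", center = c(10, 80)), "outside")
})
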