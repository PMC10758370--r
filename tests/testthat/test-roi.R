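# RoI extraction: bounding rectangles, margin expansion, bicubic resize.

test_that("bounding rectangle covers rectangle corners half-open", {
  r <- boundingRect(cbind(c(10, 30, 10, 30), c(20, 20, 60, 60)))
  expect_equal(c(r@xMin, r@yMin, r@xMax, r@yMax), c(10, 20, 31, 61))
})

test_that("bounding rectangle equals the per-axis min/max oracle on random points", {
  set.seed(14)
  for (rep in 1:5) {
    pts <- cbind(runif(200, 0, 300), runif(200, 0, 200))
    r <- boundingRect(pts)
    expect_equal(r@xMin, floor(min(pts[, 1])))
    expect_equal(r@yMin, floor(min(pts[, 2])))
    expect_equal(r@xMax, floor(max(pts[, 1])) + 1)
    expect_equal(r@yMax, floor(max(pts[, 2])) + 1)
    expect_true(all(pts[, 1] >= r@xMin & pts[, 1] < r@xMax))
    expect_true(all(pts[, 2] >= r@yMin & pts[, 2] < r@yMax))
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(boundingRect(cbind(c(1, 2), c(3, 3))), "at least 3")
  expect_error(boundingRect(cbind(c(1, 5, 9), c(3, 3, 3))), "collinear")
  expect_error(boundingRect(cbind(c(1, 2, 3), c(1, 2, 3))), "collinear")
})

test_that("margin expansion grows 8% symmetrically and clamps at edges", {
  ext <- rect(0, 0, 400, 400)
  r <- expandRect(rect(50, 50, 150, 100), 0.08, ext)
  expect_equal(rectWidth(r), 108)   # 100 + 8%
  expect_equal(rectHeight(r), 54)   # 50 + 8%

  expect_equal(expandRect(rect(50, 50, 150, 100), 0, ext),
               rect(50, 50, 150, 100))

  # touching the left edge: clamped at 0, width still at most 108
  edge <- expandRect(rect(0, 50, 100, 100), 0.08, ext)
  expect_equal(edge@xMin, 0)
  expect_lte(rectWidth(edge), 108)
  # manual arithmetic: xMax grows to ceil(100 + 4) = 104
  expect_equal(edge@xMax, 104)

  expect_error(expandRect(rect(50, 50, 500, 100), 0.08, ext), "outside")
})

test_that("expansion is monotone in the fraction and always contains the input", {
  ext <- rect(0, 0, 200, 200)
  base <- rect(37, 21, 101, 77)
  prev <- base
  for (f in c(0, 0.04, 0.08, 0.16, 0.3, 0.6)) {
    cur <- expandRect(base, f, ext)
    expect_true(cur@xMin <= prev@xMin && cur@yMin <= prev@yMin &&
                cur@xMax >= prev@xMax && cur@yMax >= prev@yMax)
    prev <- cur
  }
})

test_that("crop-resize preserves constants and identity", {
  const <- matrix(0.42, 40, 40)
  out <- cropResize(const, rect(5, 5, 30, 30), c(16, 16))
  expect_true(all(abs(out - 0.42) < 1e-12))

  img <- randomImage(32, seed = 5)
  idn <- cropResize(img, rect(0, 0, 32, 32), c(32, 32))
  expect_lt(max(abs(idn - img)), 1e-6)
})

test_that("bicubic resampling matches an independent Catmull-Rom reference", {
  # independent per-pixel implementation of the same kernel convention
  cr <- function(t, a = -0.5) {
    at <- abs(t)
    ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
      ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
  }
  refResize <- function(img, oh, ow) {
    ih <- nrow(img); iw <- ncol(img)
    out <- matrix(0, oh, ow)
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      sy <- (i - 0.5) * ih / oh - 0.5
      sx <- (j - 0.5) * iw / ow - 0.5
      acc <- 0
      for (dy in -1:2) for (dx in -1:2) {
        yy <- min(max(floor(sy) + dy, 0), ih - 1)
        xx <- min(max(floor(sx) + dx, 0), iw - 1)
        acc <- acc + img[yy + 1, xx + 1] *
          cr(sy - (floor(sy) + dy)) * cr(sx - (floor(sx) + dx))
      }
      out[i, j] <- acc
    }
    out
  }
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  up <- cropResize(ramp, rect(0, 0, 4, 4), c(8, 8))
  ref <- refResize(ramp, 8, 8)
  ref <- pmin(pmax(ref, min(ramp)), max(ramp))
  expect_lt(max(abs(up - ref)), 1e-10)

  img <- randomImage(12, seed = 8)
  got <- cropResize(img, rect(2, 1, 11, 12), c(20, 14))
  crop <- img[2:12, 3:11]
  ref2 <- pmin(pmax(refResize(crop, 14, 20), min(crop)), max(crop))
  expect_lt(max(abs(got - ref2)), 1e-10)
})

test_that("resampled output range stays within the input range", {
  img <- randomImage(24, seed = 6)
  out <- cropResize(img, rect(3, 3, 20, 20), c(40, 40))
  expect_gte(min(out), min(img[4:20, 4:20]))
  expect_lte(max(out), max(img[4:20, 4:20]))
})

test_that("extractRoi composes the stages and keeps labels", {
  d <- tinyDataset()
  res <- extractRoi(d$images[[1]], 0.08, c(32, 32))
  expect_equal(dim(res$roi), c(32, 32))
  expect_equal(res$label, d$labels[1])
  bb <- boundingRect(boundaryPoints(d$images[[1]]))
  expect_true(res$rect@xMin <= bb@xMin && res$rect@xMax >= bb@xMax)
})
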