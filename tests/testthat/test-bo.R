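# Bayesian optimisation: encoding, EI, GP surrogate, search loop.

test_that("encode/decode is the identity on sampled settings", {
  set.seed(31)
  for (i in 1:200) {
    hp <- sampleHyperParams()
    back <- decodePoint(encodeHp(hp))
    expect_equal(back@B, hp@B)
    expect_equal(back@Opt, hp@Opt)
    expect_equal(back@Mn, hp@Mn)
    expect_equal(back@Epo, hp@Epo)
    expect_equal(log10(back@Lr), log10(hp@Lr), tolerance = 1e-12)
  }
})

test_that("sampled settings respect bounds and are seed-reproducible", {
  set.seed(7)
  draws <- sampleHyperParams(1000)
  B <- vapply(draws, function(h) h@B, integer(1))
  expect_true(all(B >= 1 & B <= 5))
  Lr <- vapply(draws, function(h) h@Lr, numeric(1))
  expect_true(all(Lr >= 1e-10 & Lr <= 1e-2))
  Epo <- vapply(draws, function(h) h@Epo, integer(1))
  expect_true(all(Epo >= 50 & Epo <= 250))
  set.seed(7)
  again <- sampleHyperParams(1000)
  expect_identical(lapply(draws, encodeHp), lapply(again, encodeHp))
})

test_that("log-uniform Lr draws centre on the log-midpoint 1e-6", {
  set.seed(12)
  lr <- vapply(sampleHyperParams(10000), function(h) h@Lr, numeric(1))
  geoMean <- 10^mean(log10(lr))
  expect_gt(geoMean, 1e-6 / 2)
  expect_lt(geoMean, 1e-6 * 2)
})

test_that("expected improvement matches its closed form and limits", {
  expect_equal(expectedImprovement(0.3, 0, 0.2), 0)
  expect_equal(expectedImprovement(0.1, 0, 0.2), 0.1)
  expect_equal(expectedImprovement(0.2, 1, 0.2), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # EI >= 0 over a broad grid, and vanishes as sd -> 0 for mean >= best
  grid <- expand.grid(mean = seq(-1, 1, 0.25), sd = c(0, 0.01, 0.5, 2))
  ei <- expectedImprovement(grid$mean, grid$sd, best = 0)
  expect_true(all(ei >= 0))
  expect_true(all(expectedImprovement(c(0, 0.5, 2), 1e-12, 0) < 1e-10))
})

test_that("expected improvement agrees with a Monte-Carlo oracle", {
  set.seed(100)
  mu <- 0.5; sdev <- 0.1; best <- 0.45
  x <- rnorm(1e6, mu, sdev)
  imp <- pmax(best - x, 0)
  mc <- mean(imp); se <- sd(imp) / sqrt(length(imp))
  expect_lt(abs(expectedImprovement(mu, sdev, best) - mc), 3 * se)
})

test_that("GP posterior interpolates noise-free observations", {
  set.seed(5)
  X <- matrix(runif(30 * 7), 30, 7)
  y <- 0.2 + 0.3 * sin(3 * X[, 4]) * X[, 6]
  g <- fitSurrogate(list(X = X, y = y))
  p <- predictSurrogate(g, X)
  expect_lt(max(abs(p$mean - y)), 1e-3)
  expect_true(all(p$sd >= 0))
})

test_that("posterior variance grows away from the data", {
  set.seed(6)
  X <- matrix(runif(20 * 7, 0.4, 0.6), 20, 7)
  y <- runif(20, 0.1, 0.3)
  g <- fitSurrogate(list(X = X, y = y))
  near <- predictSurrogate(g, X)
  far <- predictSurrogate(g, matrix(3, 1, 7))
  expect_gt(far$sd, max(near$sd))
})

test_that("duplicated observations do not break the fit", {
  set.seed(8)
  X <- matrix(runif(10 * 7), 10, 7)
  X <- rbind(X, X[1, , drop = FALSE])
  y <- c(runif(10, 0, 0.5), 0.1)
  y[1] <- 0.1
  expect_no_error(g <- fitSurrogate(list(X = X, y = y)))
  expect_true(all(is.finite(predictSurrogate(g, X)$mean)))
})

test_that("fitSurrogate demands at least two observations", {
  expect_error(fitSurrogate(list(X = matrix(0.5, 1, 7), y = 0.2)),
               "at least 2")
})

test_that("proposeNext is deterministic under a seed and picks the EI argmax", {
  set.seed(17)
  obs <- lapply(1:6, function(i) {
    hp <- sampleHyperParams()
    list(hp = hp, point = encodeHp(hp), error = runif(1, 0.1, 0.4))
  })
  hist <- echonet:::newSearchHistory(obs, 17L)
  model <- fitSurrogate(hist)
  set.seed(99); a <- proposeNext(model, hist, nCandidates = 256)
  set.seed(99); b <- proposeNext(model, hist, nCandidates = 256)
  expect_identical(encodeHp(a), encodeHp(b))
  # proposals avoid exact duplicates of evaluated points (EI ~ 0 there)
  evaluated <- do.call(rbind, lapply(obs, `[[`, "point"))
  expect_false(any(apply(evaluated, 1, function(p)
    isTRUE(all.equal(p, encodeHp(a), tolerance = 1e-12)))))
})

test_that("degenerate budget equals pure random search", {
  obj <- function(hp) encodeHp(hp)[4] * 0.5 + 0.1
  h <- runSearch(obj, budget = 4, nSeed = 4, seed = 3)
  expect_length(observations(h), 4)
  errs <- vapply(observations(h), `[[`, numeric(1), "error")
  expect_equal(bestObservation(h)$error, min(errs))
  expect_equal(bestSoFar(h), cummin(errs))
})

test_that("search histories are seed-deterministic, bounded and traced", {
  obj <- function(hp) { p <- encodeHp(hp); min(1, mean((p - 0.3)^2) * 2) }
  h1 <- runSearch(obj, budget = 12, nSeed = 4, seed = 5, nCandidates = 128)
  h2 <- runSearch(obj, budget = 12, nSeed = 4, seed = 5, nCandidates = 128)
  expect_identical(historyToJson(h1), historyToJson(h2))
  expect_length(observations(h1), 12)
  expect_true(all(diff(bestSoFar(h1)) <= 0))
})

test_that("non-finite objective values are recorded as failures at error 1", {
  calls <- 0
  obj <- function(hp) {
    calls <<- calls + 1
    if (calls == 2) NaN else 0.3
  }
  expect_warning(h <- runSearch(obj, budget = 4, nSeed = 4, seed = 1),
                 "non-finite")
  errs <- vapply(observations(h), `[[`, numeric(1), "error")
  expect_equal(errs[2], 1.0)
})

test_that("histories round-trip through JSON", {
  obj <- function(hp) min(1, encodeHp(hp)[7] * 0.8 + 0.05)
  h <- runSearch(obj, budget = 8, nSeed = 4, seed = 9, nCandidates = 64)
  back <- historyFromJson(historyToJson(h))
  expect_equal(back@seed, h@seed)
  expect_equal(bestSoFar(back), bestSoFar(h))
  expect_equal(bestObservation(back)$error, bestObservation(h)$error)
  expect_identical(historyToJson(back), historyToJson(h))
})

test_that("search on a real (tiny CNN) objective beats the majority baseline", {
  d <- tinyDataset()
  idx <- c(1:30, 61:90); vidx <- c(31:45, 91:105)
  objective <- function(hp) {
    spec <- buildArchitecture(hp, inputSize = 16, baseKernels = 4)
    m <- trainModel(spec, hp, d$rois[idx], d$labels[idx],
                    d$rois[vidx], d$labels[vidx], seed = 21, maxEpochs = 4)
    m$finalValError
  }
  h <- runSearch(objective, budget = 5, nSeed = 4, seed = 2,
                 nCandidates = 128)
  expect_lt(bestObservation(h)$error, 0.5)  # majority-class error
})
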