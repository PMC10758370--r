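# Bayesian optimisation over the hyperparameter space.
#
# Settings are encoded into [0,1]^7: one-hot solver (3) + scaled log10 L2
# coefficient + scaled mini-batch index + scaled block-repeat count +
# scaled epoch budget.  A Gaussian-process surrogate (Matern 5/2 kernel
# with automatic relevance determination, small fixed noise) models the
# observed classification errors; expected improvement over the best
# observation picks the next setting from a seeded random candidate pool.
# The search evaluates `nSeed` random settings first and then
# `budget - nSeed` EI proposals.

optLevels <- c("adam", "sgdm", "rmsprop")
mnLevels <- c(32L, 64L, 128L)

#' Encode / decode hyperparameters for the surrogate
#'
#' `encodeHp` maps a setting to a numeric vector in `[0, 1]^7` (one-hot
#' solver, scaled `log10(Lr)`, scaled batch-size index, scaled `B`, scaled
#' `Epo`); `decodePoint` inverts it, rounding the discrete coordinates.
#' Decoding an encoded setting is the identity.
#'
#' @param hp a [HyperParams-class].
#' @return `encodeHp`: numeric length-7 vector; `decodePoint`: a
#'   [HyperParams-class].
#' @export
encodeHp <- function(hp) {
  onehot <- as.numeric(optLevels == hp@Opt)
  c(onehot,
    (log10(hp@Lr) + 10) / 8,
    (match(hp@Mn, mnLevels) - 1) / 2,
    (hp@B - 1) / 4,
    (hp@Epo - 50) / 200)
}

#' @rdname encodeHp
#' @param point numeric length-7 encoded vector.
#' @export
decodePoint <- function(point) {
  stopifnot(length(point) == 7L)
  hyperParams(
    B = clip(roundHalfAway(point[6] * 4 + 1), 1, 5),
    Opt = optLevels[which.max(point[1:3])],
    Lr = 10^(clip(point[4], 0, 1) * 8 - 10),
    Mn = mnLevels[clip(roundHalfAway(point[5] * 2), 0, 2) + 1],
    Epo = clip(roundHalfAway(point[7] * 200 + 50), 50, 250))
}

#' Draw random hyperparameter settings
#'
#' Uniform over `B`, the solver, the batch size and the epoch budget;
#' log-uniform over the L2 coefficient.  Consumes the current RNG stream
#' (seed the caller, e.g. via `set.seed`).
#'
#' @param n number of settings.
#' @return a single [HyperParams-class] when `n = 1`, otherwise a list.
#' @export
sampleHyperParams <- function(n = 1L) {
  draws <- lapply(seq_len(n), function(i)
    hyperParams(
      B = sample.int(5L, 1L),
      Opt = optLevels[sample.int(3L, 1L)],
      Lr = 10^stats::runif(1, -10, -2),
      Mn = mnLevels[sample.int(3L, 1L)],
      Epo = sample(50:250, 1L)))
  if (n == 1L) draws[[1]] else draws
}

#' Expected improvement for minimisation
#'
#' `EI = (best - mean) * pnorm(z) + sd * dnorm(z)` with
#' `z = (best - mean) / sd`; for `sd = 0` the limit `max(best - mean, 0)`.
#' Always non-negative.
#'
#' @param mean,sd posterior mean and standard deviation (vectorised;
#'   `sd >= 0`).
#' @param best current best (lowest) observed objective value.
#' @return expected improvement values.
#' @examples
#' expectedImprovement(0.2, 1, 0.2)  # 1/sqrt(2*pi)
#' @export
expectedImprovement <- function(mean, sd, best) {
  stopifnot(all(sd >= 0))
  d <- best - mean
  ei <- ifelse(sd > 0,
               d * stats::pnorm(d / pmax(sd, .Machine$double.eps)) +
                 sd * stats::dnorm(d / pmax(sd, .Machine$double.eps)),
               pmax(d, 0))
  pmax(ei, 0)
}

# ---- Matern 5/2 ARD Gaussian process ------------------------------------

matern52 <- function(X1, X2, lengthscales, sigma2) {
  X1s <- sweep(X1, 2, lengthscales, "/")
  X2s <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * X1s %*% t(X2s)
  r <- sqrt(pmax(d2, 0))
  s5r <- sqrt(5) * r
  sigma2 * (1 + s5r + 5 * r^2 / 3) * exp(-s5r)
}

gpNegLogLik <- function(theta, X, y, noise) {
  d <- ncol(X)
  ell <- exp(theta[seq_len(d)])
  sig2 <- exp(theta[d + 1L])^2
  K <- matern52(X, X, ell, sig2) + diag(noise, nrow(X))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

#' Fit the Gaussian-process surrogate
#'
#' Matern 5/2 kernel with per-dimension (ARD) lengthscales fitted by
#' maximising the marginal likelihood; a small fixed noise term
#' (`1e-6` on standardised targets) acts as jitter, so the posterior mean
#' interpolates noise-free observations and duplicated settings do not
#' break the factorisation.
#'
#' @param history a [SearchHistory-class] with at least 2 observations,
#'   or a list with fields `X` (encoded points, rows) and `y` (errors).
#' @param init optional warm-start vector of log kernel parameters (the
#'   `par` field of a previous fit), used by the search loop to keep
#'   refits cheap.
#' @return a `gpSurrogate` object; use [predictSurrogate()] for the
#'   posterior.
#' @export
fitSurrogate <- function(history, init = NULL) {
  if (methods::is(history, "SearchHistory")) {
    obs <- history@observations
    X <- do.call(rbind, lapply(obs, `[[`, "point"))
    y <- vapply(obs, `[[`, numeric(1), "error")
  } else {
    X <- history$X; y <- history$y
  }
  if (is.null(X) || nrow(X) < 2L)
    stop("need at least 2 observations to fit the surrogate")
  mu <- mean(y)
  sc <- stats::sd(y)
  if (!is.finite(sc) || sc < 1e-12) sc <- 1
  ys <- (y - mu) / sc
  d <- ncol(X)
  noise <- 1e-6
  if (is.null(init)) init <- c(rep(log(0.5), d), 0)
  lower <- c(rep(log(0.05), d), log(1e-3))
  upper <- c(rep(log(10), d), log(10))
  fit <- stats::optim(init, gpNegLogLik, X = X, y = ys, noise = noise,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 30, factr = 1e9))
  ell <- exp(fit$par[seq_len(d)])
  sig2 <- exp(fit$par[d + 1L])^2
  K <- matern52(X, X, ell, sig2) + diag(noise, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, yMean = mu, yScale = sc, lengthscales = ell,
                 sigma2 = sig2, noise = noise, chol = ch, alpha = alpha,
                 par = fit$par),
            class = "gpSurrogate")
}

#' Posterior mean and standard deviation of the surrogate
#'
#' @param model a `gpSurrogate` from [fitSurrogate()].
#' @param Xnew matrix of encoded points (rows) or a single numeric vector.
#' @return list with `mean` and `sd` on the original objective scale;
#'   variances are clamped at zero.
#' @export
predictSurrogate <- function(model, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Ks <- matern52(Xnew, model$X, model$lengthscales, model$sigma2)
  mean <- as.vector(Ks %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(Ks))
  var <- pmax(model$sigma2 - colSums(V^2), 0)
  list(mean = mean * model$yScale + model$yMean,
       sd = sqrt(var) * model$yScale)
}

#' Propose the next setting by expected improvement
#'
#' Scores a random candidate pool under the surrogate posterior and
#' returns the candidate with the highest expected improvement over the
#' best observation; exact ties are broken by a seeded uniform choice.
#' Consumes the current RNG stream.
#'
#' @param model a `gpSurrogate`.
#' @param history the [SearchHistory-class] so far.
#' @param nCandidates candidate-pool size (default 2048).
#' @return a [HyperParams-class].
#' @export
proposeNext <- function(model, history, nCandidates = 2048L) {
  Xc <- sampleEncodedCandidates(nCandidates)
  post <- predictSurrogate(model, Xc)
  best <- min(vapply(history@observations, `[[`, numeric(1), "error"))
  ei <- expectedImprovement(post$mean, post$sd, best)
  top <- which(ei == max(ei))
  pick <- if (length(top) > 1L) top[sample.int(length(top), 1L)] else top
  decodePoint(Xc[pick, ])
}

# vectorised candidate draw directly in the encoded space; every row is a
# valid (already snapped-to-grid) setting, identical in law to encoding
# sampleHyperParams draws
sampleEncodedCandidates <- function(n) {
  opt <- sample.int(3L, n, replace = TRUE)
  onehot <- matrix(0, n, 3)
  onehot[cbind(seq_len(n), opt)] <- 1
  cbind(onehot,
        stats::runif(n),                                # scaled log10(Lr)
        (sample.int(3L, n, replace = TRUE) - 1) / 2,    # Mn index
        (sample.int(5L, n, replace = TRUE) - 1) / 4,    # B
        (sample(0:200, n, replace = TRUE)) / 200)       # Epo
}

newSearchHistory <- function(observations, seed) {
  errs <- vapply(observations, `[[`, numeric(1), "error")
  methods::new("SearchHistory",
    observations = observations, seed = as.integer(seed),
    bestSoFar = cummin(errs), bestIndex = which.min(errs))
}

#' Run the Bayesian-optimisation search
#'
#' Evaluates `nSeed` random settings, then alternates surrogate fitting,
#' expected-improvement proposal and objective evaluation until `budget`
#' settings have been evaluated.  The setting with the lowest observed
#' classification error is the search result.  A non-finite objective
#' value is recorded as a failure with error 1 (and a warning).
#'
#' @param objective function mapping a [HyperParams-class] to a
#'   classification error in `[0, 1]`.
#' @param budget total number of evaluations (default 50).
#' @param nSeed random seed points evaluated before the surrogate starts
#'   (default 4); `budget >= nSeed >= 2`.
#' @param seed master seed for the whole search.
#' @param nCandidates EI candidate-pool size.
#' @param verbose print the best-so-far trace.
#' @return a [SearchHistory-class].
#' @export
runSearch <- function(objective, budget = 50L, nSeed = 4L, seed = 1L,
                      nCandidates = 2048L, verbose = FALSE) {
  stopifnot(budget >= nSeed, nSeed >= 2L)
  evalOne <- function(hp) {
    err <- tryCatch(objective(hp), error = function(e) NaN)
    if (!is.finite(err)) {
      warning("objective returned a non-finite value; recorded as error 1.0")
      err <- 1.0
    }
    list(hp = hp, point = encodeHp(hp), error = clip(err))
  }
  withSeed(seed, {
    obs <- lapply(seq_len(nSeed), function(i) evalOne(sampleHyperParams()))
    warm <- NULL
    while (length(obs) < budget) {
      hist <- newSearchHistory(obs, seed)
      model <- fitSurrogate(hist, init = warm)
      warm <- model$par
      hp <- proposeNext(model, hist, nCandidates)
      obs <- c(obs, list(evalOne(hp)))
      if (verbose)
        message(sprintf("eval %d: best so far %.4f", length(obs),
                        min(vapply(obs, `[[`, numeric(1), "error"))))
    }
    newSearchHistory(obs, seed)
  })
}

#' Serialize / restore a search history as JSON
#'
#' One observation per element with the decoded setting, the encoded
#' point and the error; reloading reproduces an equivalent history
#' (seed, observations, best-so-far trace).
#'
#' @param history a [SearchHistory-class].
#' @param path optional file path.
#' @return `historyToJson`: JSON string; `historyFromJson`: a
#'   [SearchHistory-class].
#' @export
historyToJson <- function(history, path = NULL) {
  payload <- list(
    seed = history@seed,
    observations = lapply(history@observations, function(o)
      list(B = o$hp@B, Opt = o$hp@Opt, Lr = o$hp@Lr, Mn = o$hp@Mn,
           Epo = o$hp@Epo, point = o$point, error = o$error)))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname historyToJson
#' @param json JSON string or file path produced by `historyToJson`.
#' @export
historyFromJson <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  obs <- lapply(p$observations, function(o)
    list(hp = hyperParams(o$B, o$Opt, o$Lr, o$Mn, o$Epo),
         point = as.numeric(unlist(o$point)),
         error = as.numeric(o$error)))
  newSearchHistory(obs, as.integer(p$seed))
}
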