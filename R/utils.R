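# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# clamp into [lo, hi]
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is banker's rounding)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a per-item 31-bit seed from a master seed; deterministic and cheap
deriveSeed <- function(master, index) {
  as.integer((as.double(master) * 2654435761 + index * 40503) %% 2147483647)
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

isImageMatrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) >= 1L && ncol(x) >= 1L
}
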