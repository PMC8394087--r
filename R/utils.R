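#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not disturb
#' the global stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-pair stream: mixes the global seed with the two frame
# indices so pairs can be processed in any order with identical results.
# Kept strictly below 2^31 - 1.
pairSeed <- function(globalSeed, ia, ib) {
  m <- 2147483629
  s <- (as.double(globalSeed) %% m) * 48271 %% m
  s <- (s + as.double(ia) * 7919 + as.double(ib) * 104729) %% m
  as.integer(s) + 1L
}

stopifnotScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite value", name), call. = FALSE)
  invisible(x)
}

# Rescale every frame of a pullback to a common [0, 255] float range using
# the pullback-wide min and max (constant pullbacks map to 0).
normalizePullback <- function(pb) {
  lo <- min(vapply(pb@frames, min, numeric(1)))
  hi <- max(vapply(pb@frames, max, numeric(1)))
  rng <- hi - lo
  fr <- if (rng <= 0) lapply(pb@frames, function(f) f * 0)
        else lapply(pb@frames, function(f) (f - lo) / rng * 255)
  pullback(fr, spacing = pb@spacing, id = pb@id)
}
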