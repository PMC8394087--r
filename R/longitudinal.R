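#' DTW configuration for the longitudinal stage
#'
#' @param C non-negative diagonal regulariser added to the vertical and
#'   horizontal predecessors of the recurrence, which favours diagonal steps
#'   and smooths the warping path; default 0.05 on the [0, 1] cost scale.
#' @param openBoundaries sub-sequence alignment (default TRUE): pullback B is
#'   consumed in full while the alignment may start and end anywhere on
#'   pullback A, which handles pairs that cover different vessel extents;
#'   FALSE forces the classical corner-to-corner alignment.
#' @param maxBand optional Sakoe-Chiba band half-width restricting |i - j|;
#'   NULL (default) leaves the warping unconstrained.
#' @return a named list of validated parameters.
#' @export
dtwConfig <- function(C = 0.05, openBoundaries = TRUE, maxBand = NULL) {
  if (C < 0) stop("'C' must be non-negative", call. = FALSE)
  if (!is.null(maxBand) && (maxBand < 0 || maxBand != round(maxBand)))
    stop("'maxBand' must be a non-negative integer or NULL", call. = FALSE)
  list(C = C, openBoundaries = isTRUE(openBoundaries),
       maxBand = if (is.null(maxBand)) NULL else as.integer(maxBand))
}

#' Pearson cross-correlation between two frames
#'
#' Correlation of the flattened pixel vectors (zero-mean, unit-norm). If both
#' frames are constant the correlation is undefined; it is defined as 0 here
#' (a constant frame carries no alignment information) with a warning.
#'
#' @param a,b numeric matrices of identical dimension.
#' @return scalar in [-1, 1].
#' @export
crossCorrelation <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("frames must have identical dimensions", call. = FALSE)
  av <- as.vector(a) - mean(a)
  bv <- as.vector(b) - mean(b)
  na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) {
    warning("constant frame: cross-correlation undefined, returning 0")
    return(0)
  }
  max(-1, min(1, sum(av * bv) / (na * nb)))
}

#' Frame dissimilarity 1 - |CC|
#'
#' The cost used by the longitudinal stage: one minus the absolute Pearson
#' cross-correlation of the two frames, always in [0, 1]. Identical and
#' perfectly anti-correlated frames both score 0; uncorrelated frames score 1.
#'
#' @param a,b numeric matrices of identical dimension.
#' @return scalar in [0, 1].
#' @export
frameDissimilarity <- function(a, b) {
  1 - abs(crossCorrelation(a, b))
}

#' Pairwise dissimilarity matrix between two pullbacks
#'
#' Entry (i, j) is \code{frameDissimilarity} between frame i of pullback A
#' and frame j of pullback B, computed in one pass by normalising the
#' flattened frames and taking a cross-product. Constant frames yield cost 1
#' against everything (dissimilarity of an undefined correlation).
#'
#' @param pa,pb [Pullback-class] objects with equal frame dimensions.
#' @return numeric N_A x N_B matrix with entries in [0, 1].
#' @export
costMatrix <- function(pa, pb) {
  stopifnot(is(pa, "Pullback"), is(pb, "Pullback"))
  if (!identical(dim(pa@frames[[1]]), dim(pb@frames[[1]])))
    stop("pullbacks must share frame dimensions", call. = FALSE)
  norm1 <- function(p) {
    m <- vapply(p@frames, as.vector, numeric(length(p@frames[[1]])))
    m <- sweep(m, 2, colMeans(m))
    nrm <- sqrt(colSums(m^2))
    list(m = sweep(m, 2, pmax(nrm, .Machine$double.eps), "/"), zero = nrm == 0)
  }
  A <- norm1(pa); B <- norm1(pb)
  cc <- crossprod(A$m, B$m)
  cc[A$zero, ] <- 0
  cc[, B$zero] <- 0
  d <- 1 - pmin(abs(cc), 1)
  d
}

#' Accumulate the regularised DTW recurrence
#'
#' Computes \code{D(i,j) = d(i,j) + min(D(i,j-1) + C, D(i-1,j) + C,
#' D(i-1,j-1))}: the vertical and horizontal predecessors carry the extra
#' regularisation cost C, the diagonal one does not. With closed boundaries
#' the first row and column accumulate with +C per step from D(1,1) = d(1,1);
#' with open boundaries the first column is initialised to the raw costs
#' d(i,1) -- the alignment may start at any frame of pullback A -- while the
#' first row still accumulates with +C per step, because every frame of
#' pullback B must be consumed (sub-sequence alignment).
#'
#' @param costs numeric cost matrix (finite entries).
#' @param config a [dtwConfig()] list.
#' @return accumulated matrix of the same shape (Inf outside the band when
#'   \code{maxBand} is set).
#' @export
dtwAccumulate <- function(costs, config = dtwConfig()) {
  if (!all(is.finite(costs))) stop("costs must be finite", call. = FALSE)
  n <- nrow(costs); m <- ncol(costs)
  C <- config$C
  D <- matrix(Inf, n, m)
  inBand <- function(i, j) is.null(config$maxBand) ||
    abs((i - 1) * (m - 1) / max(n - 1, 1) - (j - 1)) <= config$maxBand
  if (config$openBoundaries) {
    D[, 1] <- costs[, 1]
    for (j in seq_len(m)[-1]) D[1, j] <- D[1, j - 1] + costs[1, j] + C
  } else {
    D[1, 1] <- costs[1, 1]
    for (j in seq_len(m)[-1]) D[1, j] <- D[1, j - 1] + costs[1, j] + C
    for (i in seq_len(n)[-1]) D[i, 1] <- D[i - 1, 1] + costs[i, 1] + C
  }
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(m)[-1]) {
      if (!inBand(i, j)) next
      D[i, j] <- costs[i, j] +
        min(D[i, j - 1] + C, D[i - 1, j] + C, D[i - 1, j - 1])
    }
  }
  D
}

# Predecessor choice at (i, j): diagonal preferred on ties, then vertical
# (i-1, j), then horizontal (i, j-1) -- consistent with the diagonal-favouring
# regulariser and pinned for determinism.
dtwPredecessor <- function(D, i, j, C) {
  cand <- c(diag = D[i - 1, j - 1], vert = D[i - 1, j] + C,
            hori = D[i, j - 1] + C)
  names(cand)[which.min(cand)]
}

#' Backtrack the optimal warping path
#'
#' Follows, from the end cell, the predecessor attaining the minimum of the
#' recurrence (including the +C penalties), with ties broken diagonal first,
#' then vertical, then horizontal. Closed boundaries end at (N_A, N_B) and
#' stop at (1, 1); open boundaries end at the minimum of the last column
#' (pullback B fully consumed) and stop as soon as the first column is
#' entered (free start on pullback A).
#'
#' @param D accumulated matrix from [dtwAccumulate()].
#' @param config the same [dtwConfig()] used for accumulation.
#' @param costs optional cost matrix; unused in the backtrack itself but
#'   accepted for interface symmetry.
#' @return a [WarpingPath-class].
#' @export
dtwBacktrack <- function(D, config = dtwConfig(), costs = NULL) {
  n <- nrow(D); m <- ncol(D)
  if (config$openBoundaries) {
    i <- which.min(D[, m]); j <- m
  } else { i <- n; j <- m }
  path <- list(c(i, j))
  while (i > 1L || j > 1L) {
    if (config$openBoundaries && j == 1L) break
    if (i == 1L) j <- j - 1L
    else if (j == 1L) i <- i - 1L
    else {
      step <- dtwPredecessor(D, i, j, config$C)
      if (step == "diag") { i <- i - 1L; j <- j - 1L }
      else if (step == "vert") i <- i - 1L
      else j <- j - 1L
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  warpingPath(do.call(rbind, rev(path)))
}

#' Longitudinal registration of two pullbacks by dynamic time warping
#'
#' Runs the full longitudinal stage: pairwise frame dissimilarities
#' (1 - |CC|), the regularised DTW recurrence, and the backtrack. One-to-many
#' correspondences are allowed, so a frame re-sampled by catheter oscillation
#' in one pullback can match several frames of the other.
#'
#' @param pa,pb preprocessed [Pullback-class] objects (see
#'   [preprocessPullback()]).
#' @param config a [dtwConfig()] list.
#' @return list with elements \code{alignment} (a [DtwAlignment-class]) and
#'   \code{matches}, a data frame with columns \code{index_a, index_b,
#'   dissimilarity}.
#' @export
registerLongitudinal <- function(pa, pb, config = dtwConfig()) {
  d <- costMatrix(pa, pb)
  D <- dtwAccumulate(d, config)
  path <- dtwBacktrack(D, config)
  p <- pathPairs(path)
  aln <- new("DtwAlignment", cost = d, accumulated = D, path = path,
             totalCost = D[p[nrow(p), 1], p[nrow(p), 2]])
  matches <- data.frame(index_a = p[, 1], index_b = p[, 2],
                        dissimilarity = d[p])
  list(alignment = aln, matches = matches)
}
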