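#' Alignment error between a reference and a computed warping path
#'
#' The average distance from the reference correspondences to the computed
#' path: for each reference pair (i, j), the distance is the minimum of
#' |j' - j| over computed pairs (i', j') with i' = i; when index i does not
#' appear in the computed path at all (e.g. outside an open-boundary overlap)
#' the fallback is the minimum Chebyshev distance max(|i' - i|, |j' - j|)
#' over the whole computed path. The returned value is the mean over
#' reference pairs, in frames. For one-to-one paths this reduces to the
#' intuitive per-frame offset, and it handles one-to-many matches on either
#' side. Sparse landmark-style references are supported: any list of (i, j)
#' pairs works.
#'
#' @param reference a [WarpingPath-class], [DistortionRecord-class], or
#'   two-column matrix of (i, j) reference pairs.
#' @param computed a [WarpingPath-class] or two-column matrix.
#' @return mean distance in frames (non-negative scalar).
#' @export
alignmentError <- function(reference, computed) {
  ref <- asPairMatrix(reference)
  cmp <- asPairMatrix(computed)
  if (nrow(ref) == 0L) stop("reference path is empty", call. = FALSE)
  d <- vapply(seq_len(nrow(ref)), function(r) {
    i <- ref[r, 1]; j <- ref[r, 2]
    same <- cmp[, 1] == i
    if (any(same)) min(abs(cmp[same, 2] - j))
    else min(pmax(abs(cmp[, 1] - i), abs(cmp[, 2] - j)))
  }, numeric(1))
  mean(d)
}

asPairMatrix <- function(x) {
  if (is(x, "WarpingPath")) return(x@pairs)
  if (is(x, "DistortionRecord")) return(x@correspondence)
  m <- as.matrix(x)
  if (ncol(m) != 2L) stop("expected a two-column (i, j) pair matrix",
                          call. = FALSE)
  m
}

#' Normalised alignment error
#'
#' The mean alignment error divided by the number of registered frames, so
#' long and short pullbacks can be compared on one scale.
#'
#' @param meanError mean alignment error in frames.
#' @param registeredLength number of registered frames (>= 1).
#' @return dimensionless ratio.
#' @examples
#' normalizedAlignmentError(1, 115)  # 0.0087
#' @export
normalizedAlignmentError <- function(meanError, registeredLength) {
  if (registeredLength < 1) stop("'registeredLength' must be >= 1", call. = FALSE)
  meanError / registeredLength
}

#' Rotation and translation recovery error of the axial stage
#'
#' For each pair, the residual transform \code{estimated o true} (apply the
#' true perturbation, then the estimate) is computed under the shared
#' rotate-then-translate convention; a perfect estimate is the exact inverse
#' of the true perturbation and leaves an identity residual. The rotation
#' error is the absolute residual angle wrapped to (-180, 180], and the
#' translation error is the Euclidean norm of the residual translation
#' (the residual displacement of the frame centre). Millimetre statistics
#' are added when a pixel spacing is supplied.
#'
#' @param trueTransforms,estimated equal-length lists of
#'   [RigidTransform-class].
#' @param spacing optional mm per pixel.
#' @return list with \code{rotation} (mean, sd; degrees),
#'   \code{translation} (mean, sd; pixels), optional \code{translationMm},
#'   and the per-pair vectors \code{rotationErrors}, \code{translationErrors}.
#' @export
rigidError <- function(trueTransforms, estimated, spacing = NULL) {
  if (length(trueTransforms) != length(estimated))
    stop("transform lists must have equal length", call. = FALSE)
  n <- length(estimated)
  rot <- numeric(n); trans <- numeric(n)
  for (k in seq_len(n)) {
    res <- rigidCompose(estimated[[k]], trueTransforms[[k]])
    rot[k] <- abs(wrapDegrees(res@angle))
    trans[k] <- sqrt(res@tx^2 + res@ty^2)
  }
  out <- list(rotation = c(mean = mean(rot), sd = stats::sd(rot)),
              translation = c(mean = mean(trans), sd = stats::sd(trans)),
              rotationErrors = rot, translationErrors = trans)
  if (!is.null(spacing) && !is.na(spacing))
    out$translationMm <- c(mean = mean(trans) * spacing,
                           sd = stats::sd(trans) * spacing)
  out
}

wrapDegrees <- function(a) {
  w <- ((a + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Mean mutual information across the three registration settings
#'
#' Reproduces the three-setting comparison used to assess each stage:
#' (1) mean MI of frames paired index-by-index from the first frame over the
#' common length of the unregistered pullbacks, (2) mean MI over the
#' longitudinally matched frame pairs, and (3) mean MI over the axially
#' registered pairs, with the floating (pullback B) frame resampled under its
#' estimated rigid transform.
#'
#' @param pa,pb the (preprocessed) [Pullback-class] pair.
#' @param matchesLongitudinal match table from [registerLongitudinal()].
#' @param matchesAxial enriched match table from [registerAxial()] (needs the
#'   \code{angle_deg, tx_px, ty_px} columns); NULL skips setting 3.
#' @param miCfg a [miConfig()] list.
#' @return named numeric vector \code{(unregistered, longitudinal, axial)}
#'   (axial is NA when not computed).
#' @export
miThreeSettings <- function(pa, pb, matchesLongitudinal, matchesAxial = NULL,
                            miCfg = miConfig()) {
  n0 <- min(length(pa), length(pb))
  if (n0 < 1L) stop("empty overlap between pullbacks", call. = FALSE)
  miPair <- function(fb, fa) mutualInformation(fb, fa, miCfg)
  m0 <- mean(vapply(seq_len(n0), function(i)
    miPair(getFrame(pb, i), getFrame(pa, i)), numeric(1)))
  m1 <- mean(vapply(seq_len(nrow(matchesLongitudinal)), function(r)
    miPair(getFrame(pb, matchesLongitudinal$index_b[r]),
           getFrame(pa, matchesLongitudinal$index_a[r])), numeric(1)))
  m2 <- NA_real_
  if (!is.null(matchesAxial)) {
    m2 <- mean(vapply(seq_len(nrow(matchesAxial)), function(r) {
      tr <- rigidTransform(matchesAxial$angle_deg[r], matchesAxial$tx_px[r],
                           matchesAxial$ty_px[r])
      miPair(applyRigid(getFrame(pb, matchesAxial$index_b[r]), tr),
             getFrame(pa, matchesAxial$index_a[r]))
    }, numeric(1)))
  }
  c(unregistered = m0, longitudinal = m1, axial = m2)
}
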