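#' @import methods
NULL

#' Pullback: an ordered stack of 2D grayscale IVUS frames
#'
#' A pullback is the frame sequence captured while the IVUS transducer is
#' withdrawn through the vessel, here assumed already gated to end-diastole.
#' Frames are stored as numeric matrices sharing a common height and width,
#' with intensities on an arbitrary non-negative scale (typically 0-255).
#' Pixel spacing (mm per pixel) is optional; millimetre error outputs are only
#' produced when it is supplied.
#'
#' @slot frames list of numeric H x W matrices, all of identical dimension.
#' @slot spacing numeric; mm per pixel, or \code{NA_real_} when unknown.
#' @slot id character label for the pullback.
#'
#' @seealso [pullback()], [readPullback()], [writePullback()]
#' @export
setClass("Pullback",
  representation(frames = "list", spacing = "numeric", id = "character"),
  prototype(frames = list(), spacing = NA_real_, id = "pullback"))

setValidity("Pullback", function(object) {
  if (length(object@frames) < 1L)
    return("a Pullback must contain at least one frame")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    return("all frames must be 2D matrices")
  dims <- vapply(object@frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share identical dimensions")
  for (f in object@frames) {
    if (!all(is.finite(f)))
      return("frame intensities must be finite")
    if (any(f < 0))
      return("frame intensities must be non-negative")
  }
  if (length(object@spacing) != 1L)
    return("spacing must be a single value (use NA when unknown)")
  if (!is.na(object@spacing) && (!is.finite(object@spacing) || object@spacing <= 0))
    return("spacing must be a positive scalar or NA")
  TRUE
})

#' In-plane rigid transform: rotation about the frame centre plus translation
#'
#' The transform rotates by \code{angle} degrees counter-clockwise about the
#' frame centre \code{((H-1)/2, (W-1)/2)} (row, col; origin top-left), then
#' translates by \code{(tx, ty)} pixels where x is the column axis and y the
#' row axis. This rotate-then-translate order is the single convention used
#' throughout the package, including by the simulator and the error metrics.
#'
#' @slot angle numeric; rotation in degrees, counter-clockwise.
#' @slot tx numeric; translation along columns (x), pixels.
#' @slot ty numeric; translation along rows (y), pixels.
#'
#' @seealso [rigidTransform()], [applyRigid()], [rigidInverse()], [rigidCompose()]
#' @export
setClass("RigidTransform",
  representation(angle = "numeric", tx = "numeric", ty = "numeric"),
  prototype(angle = 0, tx = 0, ty = 0))

setValidity("RigidTransform", function(object) {
  v <- c(object@angle, object@tx, object@ty)
  if (length(v) != 3L || !all(is.finite(v)))
    return("angle, tx and ty must each be a finite scalar")
  TRUE
})

#' Warping path: monotone frame correspondences between two pullbacks
#'
#' The output of the dynamic-programming alignment: an ordered list of
#' (i, j) index pairs (1-based) linking frame i of pullback A to frame j of
#' pullback B. Consecutive pairs advance i, j, or both by exactly one (the
#' standard step set), so a frame of one pullback may correspond to several
#' frames of the other.
#'
#' @slot pairs two-column integer matrix of (i, j) correspondences.
#'
#' @seealso [dtwBacktrack()], [registerLongitudinal()]
#' @export
setClass("WarpingPath", representation(pairs = "matrix"))

setValidity("WarpingPath", function(object) {
  p <- object@pairs
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("pairs must be a two-column matrix with at least one row")
  if (any(p < 1L) || any(p != round(p)))
    return("indices must be positive integers")
  if (nrow(p) > 1L) {
    di <- diff(p[, 1]); dj <- diff(p[, 2])
    if (any(di < 0) || any(dj < 0))
      return("indices must be non-decreasing along the path")
    if (any(di > 1) || any(dj > 1))
      return("steps must advance i, j or both by at most 1")
    if (any(di == 0 & dj == 0))
      return("consecutive pairs must differ")
  }
  TRUE
})

#' Result of the longitudinal (DTW) alignment stage
#'
#' @slot cost numeric N_A x N_B matrix of pairwise frame dissimilarities
#'   \code{1 - |CC|}, all in [0, 1].
#' @slot accumulated numeric matrix of the same shape holding the regularised
#'   dynamic-programming recurrence values.
#' @slot path a [WarpingPath-class] through the cost matrix.
#' @slot totalCost numeric; accumulated value at the path end cell.
#'
#' @seealso [registerLongitudinal()]
#' @export
setClass("DtwAlignment",
  representation(cost = "matrix", accumulated = "matrix",
                 path = "WarpingPath", totalCost = "numeric"))

#' Ground truth produced by the synthetic-distortion simulator
#'
#' Records, for a distorted pullback derived from a base pullback, which
#' original frame every distorted frame came from, the contiguous range of
#' original frames that survived the overlap cut, and the rigid perturbation
#' applied to each distorted frame (identity transforms when the rigid
#' distortion is disabled).
#'
#' @slot correspondence two-column integer matrix (original index,
#'   distorted index), non-decreasing in the original index; every distorted
#'   frame appears exactly once.
#' @slot transforms list of [RigidTransform-class], one per distorted frame.
#' @slot keptRange integer pair (first, last) of original indices kept.
#'
#' @seealso [makeSyntheticPair()]
#' @export
setClass("DistortionRecord",
  representation(correspondence = "matrix", transforms = "list",
                 keptRange = "integer"))

setValidity("DistortionRecord", function(object) {
  cr <- object@correspondence
  if (!is.matrix(cr) || ncol(cr) != 2L)
    return("correspondence must be a two-column matrix")
  if (nrow(cr) > 1L && any(diff(cr[, 1]) < 0))
    return("correspondence must be non-decreasing in the original index")
  if (any(sort(cr[, 2]) != seq_len(nrow(cr))))
    return("every distorted frame must originate from exactly one original frame")
  if (length(object@transforms) != nrow(cr))
    return("one transform per distorted frame is required")
  if (length(object@keptRange) != 2L)
    return("keptRange must be an integer pair")
  TRUE
})

#' @describeIn Pullback-class number of frames.
#' @param x,object a \code{Pullback}.
#' @export
setMethod("length", "Pullback", function(x) length(x@frames))

#' @describeIn WarpingPath-class number of correspondence pairs.
#' @param x,object a \code{WarpingPath}.
#' @export
setMethod("length", "WarpingPath", function(x) nrow(x@pairs))

setMethod("show", "Pullback", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("Pullback '%s': %d frames of %dx%d", object@id,
              length(object@frames), d[1], d[2]))
  if (!is.na(object@spacing))
    cat(sprintf(", %.4g mm/px", object@spacing))
  cat("\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: angle %.3f deg, tx %.3f px, ty %.3f px\n",
              object@angle, object@tx, object@ty))
})

setMethod("show", "WarpingPath", function(object) {
  n <- nrow(object@pairs)
  cat(sprintf("WarpingPath: %d pairs, (%d,%d) -> (%d,%d)\n", n,
              object@pairs[1, 1], object@pairs[1, 2],
              object@pairs[n, 1], object@pairs[n, 2]))
})

setMethod("show", "DtwAlignment", function(object) {
  cat(sprintf("DtwAlignment: %dx%d cost matrix, path length %d, total cost %.4f\n",
              nrow(object@cost), ncol(object@cost), length(object@path),
              object@totalCost))
})

setMethod("show", "DistortionRecord", function(object) {
  cat(sprintf("DistortionRecord: %d distorted frames from originals %d..%d\n",
              nrow(object@correspondence), object@keptRange[1], object@keptRange[2]))
})

#' Construct a Pullback from a list of frames
#'
#' @param frames list of numeric matrices of identical dimension.
#' @param spacing optional pixel spacing in mm per pixel.
#' @param id character label.
#' @return a [Pullback-class].
#' @examples
#' pb <- pullback(list(matrix(1, 8, 8), matrix(2, 8, 8)))
#' length(pb)
#' @export
pullback <- function(frames, spacing = NA_real_, id = "pullback") {
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  new("Pullback", frames = frames, spacing = as.numeric(spacing),
      id = as.character(id))
}

#' Construct a rigid transform
#'
#' @param angle rotation in degrees, counter-clockwise about the frame centre.
#' @param tx,ty translation in pixels along the column (x) and row (y) axes.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(angle = 0, tx = 0, ty = 0) {
  new("RigidTransform", angle = as.numeric(angle), tx = as.numeric(tx),
      ty = as.numeric(ty))
}

#' Construct a warping path from an index-pair matrix
#'
#' @param pairs two-column matrix of 1-based (i, j) index pairs.
#' @return a [WarpingPath-class].
#' @export
warpingPath <- function(pairs) {
  pairs <- matrix(as.integer(round(pairs)), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  new("WarpingPath", pairs = pairs)
}

#' Accessors for pullbacks, paths and transforms
#'
#' \code{frames} returns the frame list; \code{getFrame} one frame;
#' \code{pixelSpacing} the mm-per-pixel scalar (NA when unknown);
#' \code{identifier} the label; \code{pathPairs} the (i, j) matrix of a
#' warping path; \code{transformParams} the named (angle, tx, ty) vector.
#'
#' @param x the object.
#' @param i frame index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
frames <- function(x) x@frames

#' @rdname accessors
#' @export
getFrame <- function(x, i) x@frames[[i]]

#' @rdname accessors
#' @export
pixelSpacing <- function(x) x@spacing

#' @rdname accessors
#' @export
identifier <- function(x) x@id

#' @rdname accessors
#' @export
pathPairs <- function(x) x@pairs

#' @rdname accessors
#' @export
transformParams <- function(x) c(angle = x@angle, tx = x@tx, ty = x@ty)
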