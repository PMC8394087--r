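#' Mutual-information configuration
#'
#' @param nBins histogram bins per image (>= 2); default 32, robust for 8-bit
#'   ultrasound intensities.
#' @param range optional (min, max) intensity range for binning; NULL
#'   (default) uses the joint min-max of the image pair.
#' @return a named list.
#' @export
miConfig <- function(nBins = 32L, range = NULL) {
  if (nBins < 2) stop("'nBins' must be at least 2", call. = FALSE)
  if (!is.null(range) && (length(range) != 2L || range[2] < range[1]))
    stop("'range' must be an increasing (min, max) pair or NULL", call. = FALSE)
  list(nBins = as.integer(nBins), range = range)
}

#' Apply a rigid transform to a frame
#'
#' Rotates by the transform angle counter-clockwise about the frame centre
#' \code{((H-1)/2, (W-1)/2)}, then translates by (tx, ty) pixels. Bilinear
#' interpolation; samples falling outside the frame are filled with 0. The
#' identity transform reproduces the input bit-exactly.
#'
#' @param frame numeric matrix.
#' @param transform a [RigidTransform-class].
#' @return transformed matrix of the same dimensions.
#' @export
applyRigid <- function(frame, transform) {
  stopifnot(is(transform, "RigidTransform"))
  if (!all(is.finite(frame))) stop("frame must be finite", call. = FALSE)
  cpp_apply_rigid(frame, transform@angle, transform@tx, transform@ty)
}

#' Inverse and composition of rigid transforms
#'
#' Under the rotate-then-translate convention the forward map is
#' \code{p' = R(angle)(p - c) + c + t}. The inverse is the transform
#' \code{(-angle, -R(-angle) t)}; the composition \code{a \%after\% b}
#' (apply b first, then a) is \code{(angle_a + angle_b, R(angle_a) t_b + t_a)}.
#'
#' @param t,a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
rigidInverse <- function(t) {
  th <- -t@angle * pi / 180
  rigidTransform(-t@angle,
                 tx = -(cos(th) * t@tx - sin(th) * t@ty),
                 ty = -(sin(th) * t@tx + cos(th) * t@ty))
}

#' @rdname rigidInverse
#' @export
rigidCompose <- function(a, b) {
  th <- a@angle * pi / 180
  rigidTransform(a@angle + b@angle,
                 tx = cos(th) * b@tx - sin(th) * b@ty + a@tx,
                 ty = sin(th) * b@tx + cos(th) * b@ty + a@ty)
}

#' Mutual information between two images
#'
#' Bins both images on a common nBins x nBins joint histogram over the given
#' intensity range (joint min-max of the pair by default), normalises it to a
#' joint probability table, and evaluates the double sum
#' \code{sum p(f,r) log(p(f,r) / (p(f) p(r)))} with the natural logarithm and
#' \code{0 log 0 = 0}. Symmetric and non-negative; equals the binned marginal
#' entropy when the images are identical.
#'
#' @param floating,reference numeric matrices of identical dimension.
#' @param config a [miConfig()] list.
#' @return non-negative scalar (nats).
#' @export
mutualInformation <- function(floating, reference, config = miConfig()) {
  if (!identical(dim(floating), dim(reference)))
    stop("images must have identical dimensions", call. = FALSE)
  rng <- config$range
  if (is.null(rng)) rng <- range(floating, reference)
  cpp_mutual_information(floating, reference, config$nBins, rng[1], rng[2])
}

miRange <- function(floating, reference, config) {
  if (is.null(config$range)) range(floating, reference) else config$range
}
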