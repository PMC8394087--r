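#' Distortion protocol specification
#'
#' The four distortions applied to a base pullback to manufacture a
#' registration test pair with known ground truth: (1) additive zero-mean
#' Gaussian amplitude noise, (2) partial overlap keeping a contiguous
#' 60-80\% run of frames, (3) frame repetition emulating longitudinal
#' catheter oscillation (each frame repeated with probability 0.10, 1-4 extra
#' copies), and (4) an independent per-frame rigid perturbation with rotation
#' uniform in [-15, 15] degrees and translation uniform in [-5, 5] pixels.
#'
#' @param noiseSigma Gaussian noise standard deviation in intensity units on
#'   the 0-255 scale; default 5.
#' @param overlapRange (min, max) kept fraction, default c(0.6, 0.8).
#' @param repeatProbability per-frame repetition probability, default 0.10.
#' @param repeatCountRange integer (min, max) number of extra consecutive
#'   copies of a repeated frame, default c(1, 4).
#' @param rotationRange rotation range in degrees, default c(-15, 15).
#' @param translationRange translation range in pixels per axis, default
#'   c(-5, 5).
#' @param noise,overlap,repeats,rigid logical flags enabling each distortion.
#' @param seed integer RNG seed for the pair construction.
#' @return a named list of validated parameters.
#' @export
distortionSpec <- function(noiseSigma = 5, overlapRange = c(0.6, 0.8),
                           repeatProbability = 0.10,
                           repeatCountRange = c(1L, 4L),
                           rotationRange = c(-15, 15),
                           translationRange = c(-5, 5),
                           noise = TRUE, overlap = TRUE, repeats = TRUE,
                           rigid = TRUE, seed = 1L) {
  if (noiseSigma < 0) stop("'noiseSigma' must be non-negative", call. = FALSE)
  if (length(overlapRange) != 2L || overlapRange[1] > overlapRange[2] ||
      overlapRange[1] <= 0 || overlapRange[2] > 1)
    stop("'overlapRange' must be an ordered pair in (0, 1]", call. = FALSE)
  if (repeatProbability < 0 || repeatProbability > 1)
    stop("'repeatProbability' must be in [0, 1]", call. = FALSE)
  if (length(repeatCountRange) != 2L ||
      repeatCountRange[1] > repeatCountRange[2] || repeatCountRange[1] < 1)
    stop("'repeatCountRange' must be an ordered positive integer pair",
         call. = FALSE)
  if (rotationRange[1] > rotationRange[2] ||
      translationRange[1] > translationRange[2])
    stop("rotation/translation ranges must be ordered", call. = FALSE)
  list(noiseSigma = noiseSigma, overlapRange = overlapRange,
       repeatProbability = repeatProbability,
       repeatCountRange = as.integer(repeatCountRange),
       rotationRange = rotationRange, translationRange = translationRange,
       noise = isTRUE(noise), overlap = isTRUE(overlap),
       repeats = isTRUE(repeats), rigid = isTRUE(rigid),
       seed = as.integer(seed))
}

#' Generate a phantom IVUS-like pullback
#'
#' Builds a deterministic synthetic pullback of vessel cross-sections on a
#' 0-255 intensity scale: a dark eccentric lumen inside a bright wall
#' annulus, plus axially localised anatomy the way a diseased coronary
#' presents it along a pullback -- a stenotic segment where the lumen
#' narrows and the plaque arc thickens, a calcific segment (very bright arc
#' with a distal acoustic shadow), and a bifurcation segment (an echo-poor
#' wedge opening in the wall). Angular positions stay nearly fixed (small
#' slow wobble, as a catheter slowly twists), while radii, thickness,
#' eccentricity and the axial envelopes of the lesions drift smoothly from
#' frame to frame, so neighbouring frames are similar but distinct and the
#' axial signature does not masquerade as an in-plane rotation.
#' Gamma-distributed multiplicative speckle (unit mean) is applied per
#' frame, mimicking the granular texture of ultrasound.
#'
#' @param nFrames number of frames (>= 1).
#' @param size (height, width) in pixels; default c(128, 128).
#' @param seed integer seed; the same seed reproduces the pullback
#'   bit-identically.
#' @param spacing optional mm-per-pixel to attach.
#' @return a [Pullback-class].
#' @examples
#' pb <- generatePhantomPullback(5, c(64, 64), seed = 7)
#' length(pb)
#' @export
generatePhantomPullback <- function(nFrames, size = c(128L, 128L), seed = 1L,
                                    spacing = NA_real_) {
  if (nFrames < 1) stop("'nFrames' must be at least 1", call. = FALSE)
  H <- size[1]; W <- size[2]
  withSeed(seed, {
    # anatomical position advances per frame (catheter travel per gated
    # frame), not per pullback: a 40-frame phantom is a shorter vessel
    # segment with the same frame-to-frame change as a full ~118-frame
    # pullback
    t <- (seq_len(nFrames) - 1) / 117
    tMax <- max(t[nFrames], 1e-6)
    ph <- stats::runif(12, 0, 2 * pi)      # random phases of the slow drifts
    # axial centres and widths of the three lesion segments (in t units)
    sSten <- stats::runif(1, 0.1, 0.9) * tMax; wSten <- stats::runif(1, 0.06, 0.12)
    sCalc <- stats::runif(1, 0.1, 0.9) * tMax; wCalc <- stats::runif(1, 0.05, 0.10)
    sBif <- stats::runif(1, 0.1, 0.9) * tMax; wBif <- stats::runif(1, 0.04, 0.08)
    thPlaque <- stats::runif(1, 0, 2 * pi)  # fixed angular anatomy
    thCalc <- stats::runif(1, 0, 2 * pi)
    thBif <- stats::runif(1, 0, 2 * pi)
    # slow catheter twist and breathing-scale wobbles
    twist <- 0.35 * sin(2 * pi * t * 0.6 + ph[1])
    cx <- (W - 1) / 2 + 0.03 * W * sin(2 * pi * t * 0.8 + ph[2])
    cy <- (H - 1) / 2 + 0.03 * H * cos(2 * pi * t * 0.5 + ph[3])
    sten <- exp(-((t - sSten) / wSten)^2)   # axial envelopes
    calc <- exp(-((t - sCalc) / wCalc)^2)
    bif <- exp(-((t - sBif) / wBif)^2)
    # radial anatomy varies on a 10-25 frame scale (plaque burden and lumen
    # calibre change over a few mm of vessel), giving every cross-section a
    # rotation-invariant radial signature
    lumenR <- W * (0.16 + 0.035 * sin(2 * pi * t * 2.1 + ph[4]) +
                     0.03 * sin(2 * pi * t * 7.9 + ph[7])) *
      (1 - 0.45 * sten)
    wallR <- W * (0.30 + 0.03 * sin(2 * pi * t * 1.4 + ph[5]) +
                    0.02 * sin(2 * pi * t * 3.3 + ph[6]) +
                    0.02 * sin(2 * pi * t * 5.3 + ph[8]))
    # gated frames sit a cardiac cycle (~0.5-1 mm of travel) apart, so
    # consecutive frames also fluctuate: gating jitter and residual cardiac
    # motion modulate apparent calibre, ring position and echogenicity with
    # a ~1-frame correlation scale; these fluctuations are rotation
    # invariant, exactly like the per-frame appearance changes of real
    # gated pullbacks
    ringPos <- 0.78 + 0.06 * sin(2 * pi * t * 4.7 + ph[9]) +
      0.20 * arSeries(nFrames, 0.5)
    lumenR <- lumenR * (1 + 0.13 * arSeries(nFrames, 0.5))
    wallGain <- 1 + 0.25 * arSeries(nFrames, 0.5)
    wallR <- wallR * (1 + 0.06 * arSeries(nFrames, 0.5))
    plaqueGain <- 30 + 18 * sin(2 * pi * t * 6.1 + ph[10]) +
      20 * arSeries(nFrames, 0.5)
    plaqueW <- 1.1 + 0.5 * sin(2 * pi * t * 3.7 + ph[11]) + 1.4 * sten
    ecc <- 0.18 + 0.25 * sten
    xg <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    yg <- matrix(rep(seq_len(H) - 1, W), H, W)
    frames <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      dx <- xg - cx[f]; dy <- yg - cy[f]
      r <- sqrt(dx^2 + dy^2)
      a <- atan2(dy, dx) - twist[f]
      # eccentric lumen, pushed off-centre away from the plaque
      lr <- lumenR[f] * (1 + ecc[f] * cos(a - thPlaque))
      img <- 25 + 15 * exp(-((r - wallR[f] * 1.6) / (0.25 * W))^2)  # adventitia glow
      img[r < lr] <- 6                                              # lumen blood
      # thin bright leading-edge echo (intima/stent-like) whose radius
      # fluctuates frame to frame; narrow relative to its jitter, so each
      # cross-section has a distinctive, rotation-invariant ring signature
      wall <- r >= lr & r < wallR[f]
      img[wall] <- wallGain[f] *
        (110 + 90 * exp(-((r[wall] - wallR[f] * ringPos[f]) / (0.05 * W))^2))
      # plaque: thickened, moderately bright arc between lumen and wall
      inPlaque <- wall & (abs(wrapAngle(a - thPlaque)) < plaqueW[f] / 2)
      img[inPlaque] <- img[inPlaque] + plaqueGain[f] + 40 * sten[f]
      # calcific segment: very bright arc at the wall with a distal shadow
      if (calc[f] > 0.2) {
        inCalc <- abs(wrapAngle(a - thCalc)) < 0.35 * calc[f] + 0.1 &
          abs(r - wallR[f] * 0.85) < 0.05 * W
        img[inCalc] <- 250
        shadow <- abs(wrapAngle(a - thCalc)) < 0.3 * calc[f] + 0.08 &
          r >= wallR[f] * 0.9
        img[shadow] <- img[shadow] * 0.45
      }
      # bifurcation segment: echo-poor wedge opening through the wall
      if (bif[f] > 0.2) {
        gap <- abs(wrapAngle(a - thBif)) < 0.55 * bif[f] & r >= lr
        img[gap] <- 12
      }
      # multiplicative speckle with a realistic multi-pixel resolution cell,
      # then the log-compression display mapping of B-mode scan converters
      # (which is what clinical IVUS frames actually show; it lifts the dark
      # range and flattens bright-region speckle contrast)
      img <- img * speckleField(H, W)
      img <- 255 * log1p(30 * img / 255) / log1p(30)
      frames[[f]] <- pmin(pmax(img, 0), 255)
    }
    pullback(frames, spacing = spacing,
             id = sprintf("phantom-seed%d", as.integer(seed)))
  })
}

wrapAngle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

# Stationary AR(1) series with unit marginal variance; correlation rho
# between consecutive frames. Draws from the current RNG stream.
arSeries <- function(n, rho) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  if (n > 1)
    for (f in 2:n)
      x[f] <- rho * x[f - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
  x
}

# Unit-mean multiplicative speckle: fully developed speckle has
# exponentially distributed intensity, and the grain size is the imaging
# resolution cell (a few pixels), so an exponential field is blurred with a
# separable binomial kernel of radius 2 (~3 px correlation length). The
# smoothing leaves a relative sd of ~27%. Draws from the current RNG stream.
speckleField <- function(H, W) {
  g <- matrix(stats::rexp(H * W), H, W)
  k <- c(1, 4, 6, 4, 1) / 16
  blur1 <- function(m) {
    n <- nrow(m)
    p <- rbind(m[rep(1, 2), , drop = FALSE], m,
               m[rep(n, 2), , drop = FALSE])
    k[1] * p[1:n, ] + k[2] * p[2:(n + 1), ] + k[3] * p[3:(n + 2), ] +
      k[4] * p[4:(n + 3), ] + k[5] * p[5:(n + 4), ]
  }
  s <- t(blur1(t(blur1(g))))
  s / mean(s)
}

#' Amplitude distortion: additive zero-mean Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) noise per pixel, clipped to the valid [0, 255]
#' intensity range. Draws from the current RNG stream.
#'
#' @param pb a [Pullback-class].
#' @param sigma noise standard deviation (>= 0).
#' @return the noisy [Pullback-class].
#' @export
distortAmplitude <- function(pb, sigma) {
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) return(pb)
  fr <- lapply(pb@frames, function(f)
    pmin(pmax(f + matrix(stats::rnorm(length(f), 0, sigma), nrow(f)), 0), 255))
  pullback(fr, spacing = pb@spacing, id = pb@id)
}

#' Overlap distortion: keep a contiguous 60-80% run of frames
#'
#' Draws the kept fraction u uniformly from \code{overlapRange}, keeps
#' \code{round(L u)} consecutive frames, and splits the discarded amount
#' randomly between the head and the tail. Draws from the current RNG stream.
#'
#' @param pb a [Pullback-class] with at least 5 frames.
#' @param overlapRange (min, max) kept fraction in (0, 1].
#' @return list with the cropped \code{pullback} and \code{keptRange}, the
#'   (first, last) original indices kept.
#' @export
distortOverlap <- function(pb, overlapRange = c(0.6, 0.8)) {
  L <- length(pb)
  if (L < 5L) stop("pullback must have at least 5 frames", call. = FALSE)
  u <- stats::runif(1, overlapRange[1], overlapRange[2])
  keep <- round(L * u)
  if (keep < 1L) stop("overlap range implies zero kept frames", call. = FALSE)
  head <- sample.int(L - keep + 1L, 1L) - 1L
  first <- head + 1L
  last <- head + keep
  list(pullback = pullback(pb@frames[first:last], spacing = pb@spacing,
                           id = pb@id),
       keptRange = c(first = first, last = last))
}

#' Longitudinal distortion: random frame repetition
#'
#' Each frame is independently selected with \code{repeatProbability}; a
#' selected frame is inserted 1-4 (uniform integer over
#' \code{repeatCountRange}) extra consecutive times, emulating re-sampling of
#' the same cross-section by catheter oscillation. Draws from the current RNG
#' stream.
#'
#' @param pb a [Pullback-class].
#' @param repeatProbability per-frame selection probability.
#' @param repeatCountRange integer (min, max) extra copies.
#' @return list with the expanded \code{pullback} and \code{correspondence},
#'   an integer vector mapping every output frame to its input frame index.
#' @export
distortRepeat <- function(pb, repeatProbability = 0.10,
                          repeatCountRange = c(1L, 4L)) {
  L <- length(pb)
  sel <- stats::runif(L) < repeatProbability
  extra <- integer(L)
  nsel <- sum(sel)
  counts <- seq(repeatCountRange[1], repeatCountRange[2])
  if (nsel > 0)
    extra[sel] <- if (length(counts) == 1L) rep(counts, nsel)
                  else sample(counts, nsel, replace = TRUE)
  corr <- rep(seq_len(L), times = 1L + extra)
  list(pullback = pullback(pb@frames[corr], spacing = pb@spacing, id = pb@id),
       correspondence = corr)
}

#' Rigid distortion: independent per-frame rotation and translation
#'
#' Each frame receives an independent rigid perturbation with rotation drawn
#' uniformly from \code{rotationRange} and each translation component drawn
#' uniformly from \code{translationRange}, applied with [applyRigid()].
#' Draws from the current RNG stream.
#'
#' @param pb a [Pullback-class].
#' @param rotationRange rotation range in degrees.
#' @param translationRange per-axis translation range in pixels.
#' @return list with the perturbed \code{pullback} and \code{transforms}, a
#'   list of the applied [RigidTransform-class] per frame.
#' @export
distortRigid <- function(pb, rotationRange = c(-15, 15),
                         translationRange = c(-5, 5)) {
  L <- length(pb)
  transforms <- vector("list", L)
  fr <- vector("list", L)
  for (f in seq_len(L)) {
    tr <- rigidTransform(stats::runif(1, rotationRange[1], rotationRange[2]),
                         stats::runif(1, translationRange[1], translationRange[2]),
                         stats::runif(1, translationRange[1], translationRange[2]))
    transforms[[f]] <- tr
    fr[[f]] <- applyRigid(pb@frames[[f]], tr)
  }
  list(pullback = pullback(fr, spacing = pb@spacing, id = pb@id),
       transforms = transforms)
}

#' Build a synthetic registration pair with full ground truth
#'
#' Applies the enabled distortions to a base pullback in the order overlap ->
#' repeat -> rigid -> amplitude (so the additive noise is the last operation
#' on each emitted frame and repeated copies receive independent rigid and
#' noise draws), and assembles the ground truth against the unmodified base:
#' the (original, distorted) frame correspondence, the kept range, and the
#' per-frame rigid perturbations. The reference member of the pair is the
#' full-length base pullback itself.
#'
#' @param base a [Pullback-class] of length >= 5.
#' @param spec a [distortionSpec()] list; its seed makes the pair
#'   reproducible bit-exactly.
#' @return list with \code{reference}, \code{distorted} (both
#'   [Pullback-class]) and \code{record} (a [DistortionRecord-class]).
#' @export
makeSyntheticPair <- function(base, spec = distortionSpec()) {
  stopifnot(is(base, "Pullback"))
  if (length(base) < 5L)
    stop("base pullback must have at least 5 frames", call. = FALSE)
  withSeed(spec$seed, {
    kept <- c(first = 1L, last = length(base))
    cur <- base
    if (spec$overlap) {
      ov <- distortOverlap(cur, spec$overlapRange)
      cur <- ov$pullback
      kept <- ov$keptRange
    }
    corr <- seq_len(length(cur))
    if (spec$repeats) {
      rp <- distortRepeat(cur, spec$repeatProbability, spec$repeatCountRange)
      cur <- rp$pullback
      corr <- rp$correspondence
    }
    L <- length(cur)
    transforms <- replicate(L, rigidTransform(0, 0, 0), simplify = FALSE)
    if (spec$rigid) {
      rg <- distortRigid(cur, spec$rotationRange, spec$translationRange)
      cur <- rg$pullback
      transforms <- rg$transforms
    }
    if (spec$noise)
      cur <- distortAmplitude(cur, spec$noiseSigma)
    correspondence <- cbind(original = kept["first"] + corr - 1L,
                            distorted = seq_len(L))
    dimnames(correspondence) <- list(NULL, c("original", "distorted"))
    record <- new("DistortionRecord",
                  correspondence = correspondence,
                  transforms = transforms,
                  keptRange = as.integer(kept))
    list(reference = base,
         distorted = pullback(cur@frames, spacing = base@spacing,
                              id = paste0(base@id, "-distorted")),
         record = record)
  })
}
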