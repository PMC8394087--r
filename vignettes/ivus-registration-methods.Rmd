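---
title: "Registering IVUS pullback pairs: methods and design notes"
author: "ivusreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering IVUS pullback pairs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivusreg)
```

## The problem

Intravascular ultrasound (IVUS) images a coronary artery from the inside: a
transducer on a catheter is withdrawn through the vessel and records a stack
of cross-sectional frames (a *pullback*). Comparing two pullbacks of the same
vessel — before and after stenting, or baseline versus follow-up — requires
knowing which frame corresponds to which, and how each matched pair is
rotated and shifted in plane. Neither is given: the two acquisitions start
and end at different positions (partial overlap), the catheter oscillates
axially with the heartbeat so some cross-sections are sampled several times,
and the catheter rotates freely in the lumen between acquisitions.

`ivusreg` registers a pair of end-diastole-gated pullbacks in two stages:

1. **Longitudinal registration** — dynamic time warping (DTW) over an
   image-level dissimilarity matches frames along the vessel axis, allowing
   one-to-many correspondences.
2. **Axial registration** — each matched frame pair is aligned in plane by a
   rigid transform (rotation about the frame centre plus translation) that
   maximises mutual information (MI), optimised with a Harmony Search
   variant.

Gating itself (selecting one end-diastolic frame per cardiac cycle) is out of
scope; input pullbacks are assumed already gated.

## Preprocessing

Each frame of both pullbacks passes through two filters
(`preprocessPullback()`):

* **CDF-percentile threshold** (`thresholdCdf()`): pixels strictly below the
  90th percentile of the frame's empirical intensity distribution are set to
  zero. This removes low-intensity artifacts (blood speckle, near-field
  halo) and concentrates the dissimilarity measure on the bright wall
  structures. The percentile value uses the linear-interpolation estimator
  (`quantile()` type 7), pinned for reproducibility; zeroing (rather than
  clipping) is deliberate — the artifact content is discarded entirely. The
  operation is idempotent at a fixed percentile.
* **Perona–Malik anisotropic diffusion** (`anisotropicDiffusion()`):
  an explicit 4-neighbour scheme with exponential conductance
  `g(s) = exp(-(s/kappa)^2)`, time step `lambda = 0.15` (within the 0.25
  stability bound), `kappa = 30` intensity units on 0–255-scaled data, 10
  iterations. Gradients well above `kappa` (structural edges) diffuse
  little; homogeneous regions are smoothed. Boundaries are replicated, so no
  artificial edge forms at the frame border and the global mean is
  conserved exactly.

Intensities are first rescaled per pullback to a common [0, 255] float range,
so the `kappa` default has a fixed meaning regardless of the input scale.

## Longitudinal stage

The frame dissimilarity is `d(i, j) = 1 − |CC(i, j)|`, where CC is the
Pearson correlation of the flattened pixel vectors of frames *i* (pullback A)
and *j* (pullback B). The absolute value makes contrast inversions
equivalent; values lie in [0, 1]. Constant frames, whose correlation is
undefined, are assigned CC = 0 (cost 1): a flat frame carries no alignment
information. The full matrix is computed as one cross-product of normalised
frame vectors (`costMatrix()`).

The accumulated cost follows the regularised recurrence

```
D(i,j) = d(i,j) + min( D(i,j−1) + C,  D(i−1,j) + C,  D(i−1,j−1) )
```

with `C = 0.05` by default on the [0, 1] cost scale: vertical and horizontal
predecessors — the steps that create one-to-many matches — carry an extra
cost, so the path favours the diagonal and stays smooth. Ties in the minimum
break diagonal, then vertical, then horizontal, pinned for determinism.

**Boundary conditions.** Because the two pullbacks generally cover different
vessel extents, the default alignment is *open* (`dtwConfig(openBoundaries =
TRUE)`) with sub-sequence semantics: every frame of pullback B must be
consumed (the first row accumulates with +C per step), while the alignment
may start and end at any frame of pullback A (the first column holds the raw
costs and the end cell is the minimum of the last column). We initially
evaluated a symmetric variant with free starts and ends on both sequences
and found it ill-posed: a cell in the first column of the last row is
simultaneously a legal start and end, so degenerate paths of one or two
lucky cells can undercut any genuine alignment, with or without
length-normalisation of the accumulated cost. Requiring full consumption of
one designated sequence — the convention sub-sequence DTW implementations
use — removes the degeneracy, and fits the pipeline's orientation: pass the
longer or reference pullback as A. The classical corner-to-corner alignment
remains available with `openBoundaries = FALSE`.

## Axial stage

For a matched pair, the floating frame (from B) is resampled under a
candidate rigid transform (`applyRigid()`: rotation about the frame centre
`((H−1)/2, (W−1)/2)`, then translation; bilinear interpolation; zero fill)
and compared to the reference frame by mutual information: a 32×32-bin joint
intensity histogram over the pair's min–max range, normalised to a joint
probability table, natural logarithm, `0·log 0 = 0`. MI is symmetric,
non-negative, insensitive to the monotone intensity distortions that defeat
correlation, and — the optimised quantity being base-invariant — the
logarithm base is immaterial. The joint binning range and 32-bin default are
pinned; 32 bins is a robust choice for 8-bit ultrasound.

The MI surface over (angle, tx, ty) is non-convex, so it is maximised with a
population metaheuristic, Harmony Search, modified in two ways
(`harmonySearch()`):

* **Construction rule.** Each element of a new candidate is, with
  probability `h(1−p)`, copied from a uniformly chosen memory solution; with
  probability `h·p`, copied and perturbed by a tuning step *e*; and with
  probability `1−h`, drawn uniformly from the search bounds. `h` rises
  linearly 0.7 → 0.95 and `p` 0.1 → 0.5 over the run, shifting from
  exploration to exploitation.
* **ALOPEX-style tuning step.** Instead of a blind random step, the sign of
  *e* in each dimension is biased (probability 0.75) toward the direction of
  the most recent objective improvement — the sign of `Δx_i · ΔJ` between
  the last two evaluated candidates, the correlation rule of ALOPEX — and
  its magnitude is `|N(0,1)|` scaled by each dimension's bound range, a step
  scale of 0.05, and an annealing temperature that decays by 0.99 per
  iteration. With fewer than two evaluations on record the step falls back
  to a uniform draw within ±1% of the bound range.

Defaults: memory 20, 500 candidate constructions, bounds angle ∈ [−20°, 20°]
and translation ∈ [−8, 8] px — slightly wider than the simulator's
perturbation ranges so a true optimum never sits on the search boundary.
The identity transform is always seeded into the initial memory and
candidates only replace strictly worse entries, so the returned transform
never scores below the identity (`mi_after ≥ mi_before` up to ties). Each
frame pair draws its RNG stream from `(seed, index_a, index_b)`, making
results independent of processing order and bit-reproducible.

## Synthetic data generator

Clinical pullback pairs with ground truth are not distributable, so the
package carries a simulator that manufactures test pairs from a phantom
pullback, with the registration answer known exactly.

`generatePhantomPullback()` renders vessel cross-sections on a 0–255 scale:
a dark eccentric lumen in a bright wall, a thin bright leading-edge echo
(intima/stent-like ring), and three axially localised lesion segments — a
stenosis (lumen narrows, plaque arc widens and brightens), a calcific arc
(very bright, with a distal acoustic shadow), and a bifurcation (echo-poor
wedge through the wall) — at fixed angular positions with a slow catheter
twist. Two timescales of variation give each frame an identity:

* smooth drifts of radii, eccentricity and arc geometry along the pullback
  (the anatomy, advancing *per frame* so a 40-frame phantom is simply a
  shorter vessel segment, not a compressed one); and
* per-frame AR(1) fluctuations (lag-1 correlation 0.5) of lumen calibre,
  ring radius and echogenicity, emulating gating jitter and residual cardiac
  motion between frames captured a full cardiac cycle apart.

The second ingredient matters: consecutive gated frames of real pullbacks
are noticeably different, and most of that difference is *rotation
invariant* (calibre, thickness, echogenicity). Early versions of the phantom
carried their frame identity mainly in arc positions, and an in-plane
rotation then mimicked an axial shift, which no intensity-based method could
disambiguate. Speckle is multiplicative with exponentially distributed
intensity blurred to a ~3-pixel resolution cell, followed by B-mode log
compression — the display mapping clinical IVUS frames actually undergo.

`makeSyntheticPair()` applies four distortions in the order overlap →
repetition → rigid → noise (so noise is the last operation on each emitted
frame, and repeated copies receive independent rigid and noise draws,
simulating re-sampling of one cross-section at different catheter poses):

1. additive zero-mean Gaussian noise, σ = 5 on the 0–255 scale;
2. partial overlap: a contiguous run of `round(L·u)` frames kept,
   u ~ U(0.6, 0.8), the cut split randomly between head and tail;
3. repetition: each frame with probability 0.10 inserted 1–4 extra
   consecutive times (uniform integer);
4. an independent per-frame rigid perturbation, rotation U(−15°, 15°) and
   translation U(−5, 5) px per axis.

The returned `DistortionRecord` carries the exact correspondence, the kept
range and every applied transform, so both stages can be scored.

## Error metrics

* **Alignment error** (`alignmentError()`): for each ground-truth pair
  (i, j), the distance to the computed path is the minimum |j′ − j| over
  path pairs with i′ = i, falling back to the Chebyshev distance
  max(|i′−i|, |j′−j|) when index i is absent from the path; the reported
  value is the mean, in frames. For one-to-one paths this is the intuitive
  frame offset; the same rule scores sparse landmark references. The
  normalised variant divides by the number of registered frames.
* **Rigid recovery error** (`rigidError()`): the residual transform
  `estimated ∘ true` is computed under the package's single
  rotate-then-translate convention; a perfect estimate is the exact inverse
  of the perturbation. Rotation error is the absolute residual angle wrapped
  to (−180°, 180°]; translation error is the Euclidean norm of the residual
  translation (the residual displacement of the frame centre). Millimetre
  figures appear only when a pixel spacing is supplied — none is ever
  assumed.
* **Three-setting MI** (`miThreeSettings()`): mean MI over index-paired
  frames of the unregistered pullbacks, over the longitudinally matched
  pairs, and over the axially registered pairs, quantifying the gain of each
  stage.

Note one property of the recovery metric: it is computed over *matched*
pairs, so when the warping path assigns a frame to an axial neighbour of its
true origin, the residual conflates the (well-recovered) perturbation with
genuine anatomical difference. Correctly matched pairs recover to a few
tenths of a degree; the pooled mean is dominated by the small mismatched
fraction. The published synthetic results show the same signature (a
standard deviation roughly twice the mean).

## Experiment driver and problem sizes

`runSyntheticExperiment()` reproduces the synthetic protocol end to end:
phantom bases, distorted copies, two-stage registration, and aggregation of
alignment / rotation / translation errors, all derived deterministically
from one seed. The package's own validation uses two configurations, chosen
to exercise the method at realistic dimensions while keeping a laptop-scale
run: ten pairs of 118-frame pullbacks (the typical gated pullback length) at
128×128 with distortions 1–3 for the longitudinal stage alone, and five
pairs of 40-frame pullbacks at 128×128 with all four distortions for the
full pipeline — about 200 Harmony-Search registrations of 500 MI evaluations
each. `scripts/acceptance.R` re-runs both from a command-line seed.

## What the synthetic tests do and do not show

The simulator provides exact ground truth and reproduces the artifact
structure the method must overcome (partial overlap, re-sampled frames,
in-plane rigid motion, speckle). It does not reproduce everything that makes
clinical pairs hard: the two pullbacks of a real pair are separate
acquisitions (independent speckle realisations, different gain settings,
possibly months apart with true disease progression and stent placement),
vessels deform non-rigidly with the cardiac residual, and gating is
imperfect. Passing the synthetic experiments therefore validates the
implementation and the method's behaviour under the modelled distortions; it
does not certify clinical-grade accuracy, where published in-vivo errors are
roughly an order of magnitude larger than synthetic ones.

## Numerical choices and degenerate inputs

* Tie-breaks: DTW predecessor diagonal ≻ vertical ≻ horizontal; Harmony
  memory replacement only on strict improvement (so exact ties keep the
  incumbent, and self-registration returns the exact identity).
* Constant frames: CC undefined → defined as 0 with a warning; MI against a
  constant image is 0 (degenerate marginal).
* The phantom intensity scale, the MI binning range and the preprocessing
  normalisation all use the 0–255 convention; `writePullback()` stores
  integer-valued frames as 16-bit TIFF pages (bit-exact round-trip for 8-bit
  data) and float frames as 32-bit float pages scaled to [0, 1].
* All stochastic components (phantom, distortions, optimiser) draw from
  seeds derived by a fixed integer mixing function, kept below 2^31, so any
  experiment is reproducible bit-exactly and independent of evaluation
  order.

## Known limitations

* The longitudinal cost is purely intensity-based by design (no lumen or
  plaque segmentation); pullbacks whose appearance changes drastically
  between acquisitions will degrade the warping path, and every axial error
  on a mismatched pair inherits that degradation.
* Rigid in-plane alignment cannot capture vessel deformation; residual
  non-rigid differences persist after registration.
* The sub-sequence boundary convention assumes one pullback's extent
  roughly contains the other's overlap region; for pairs with genuinely
  disjoint head/tail overhangs on both sides, the overhang of B is still
  forced onto A's edge frames.
* DICOM ingestion, ECG gating and 3D reconstruction are out of scope.
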