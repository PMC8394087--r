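# ivusreg

Two-stage registration of paired intravascular ultrasound (IVUS) pullbacks.

Serial IVUS examinations of a coronary artery — before and after stent
deployment, or baseline and follow-up — produce pairs of frame stacks
("pullbacks") that cover different vessel extents, sample some
cross-sections repeatedly because the catheter oscillates with the
heartbeat, and disagree on in-plane orientation because the catheter rotates
freely in the lumen. Comparing such pairs frame by frame is the everyday
problem of anyone assessing atherosclerosis progression or an intervention's
result from sequential imaging. `ivusreg` automates the comparison for
end-diastole-gated pullbacks using only global, intensity-level measurements
(no lumen or plaque segmentation):

1. **Longitudinal registration.** Frames are matched along the vessel axis
   by dynamic time warping over the dissimilarity
   `d(i,j) = 1 − |CC(i,j)|` (Pearson cross-correlation of the two frames),
   accumulated with the regularised recurrence
   `D(i,j) = d(i,j) + min(D(i,j−1)+C, D(i−1,j)+C, D(i−1,j−1))`, whose
   penalty `C` favours diagonal steps and keeps the warping path smooth.
   One-to-many matches are allowed; boundaries are open by default
   (sub-sequence alignment), so partial overlap is handled.
2. **Axial registration.** Every matched frame pair is aligned by an
   in-plane rigid transform (rotation about the frame centre, then
   translation) maximising mutual information
   `MI = Σ p(f,r) log[ p(f,r) / (p(f) p(r)) ]` over a 32×32-bin joint
   intensity histogram. The non-convex MI surface is searched with a
   Harmony Search variant whose tuning step is sign-biased by the recent
   objective trend (an ALOPEX-style correlation rule) and whose
   memory-consideration and pitch-adjustment rates increase over the run.

Frames are preprocessed beforehand (90th-percentile CDF threshold, then
Perona–Malik anisotropic diffusion) to suppress blood speckle and
low-intensity artifacts. A synthetic-distortion simulator — phantom
pullbacks plus Gaussian noise, 60–80 % partial overlap, 10 % frame
repetition, and per-frame rigid perturbations within ±15° / ±5 px — provides
ground truth for validating both stages without clinical data, and the
matching error metrics (warping-path alignment error, rotation/translation
recovery error, mean MI per registration stage) are included.

## Worked example

```r
library(ivusreg)

# a 60-frame phantom pullback and a distorted copy with known ground truth
base <- generatePhantomPullback(60, c(128, 128), seed = 7)
pair <- makeSyntheticPair(base, distortionSpec(seed = 8))
pair$distorted
#> Pullback 'phantom-seed7-distorted': 51 frames of 128x128

res <- registerPullbacks(pair$reference, pair$distorted,
                         hsCfg = harmonyConfig(seed = 9))
res$longitudinal$alignment
#> DtwAlignment: 60x51 cost matrix, path length 51, total cost 24.3792
head(res$matches, 3)
#>   index_a index_b dissimilarity angle_deg     tx_px      ty_px  mi_before  mi_after
#> 1       2       1     0.7002806 12.293741  3.015973  5.0714861 0.03469635 0.3027180
#> 2       3       2     0.5711555 10.564427  2.356406 -4.3537258 0.06912778 0.3335344
#> 3       4       3     0.4212146  6.825722 -2.325431  0.9657373 0.11277711 0.3275335

# score against the simulator's ground truth
alignmentError(pair$record, res$longitudinal$alignment@path)
#> [1] 0
err <- rigidError(pair$record@transforms[res$matches$index_b], res$transforms)
#> rotation error: 0.22 +/- 0.33 deg
#> translation error: 0.15 +/- 0.11 px
miThreeSettings(res$preprocessedA, res$preprocessedB,
                res$longitudinal$matches, res$matches)
#> unregistered longitudinal        axial
#>        0.052        0.107        0.343
```

Reading: the distorted pullback kept 51 of 60 frames; the warping path
recovered every ground-truth correspondence (alignment error 0 frames); the
axial stage recovered the per-frame rigid perturbations to 0.22° and
0.15 px on average; and the mean mutual information of matched frames rises
at each registration stage, from 0.052 (unregistered) through 0.107
(longitudinally matched) to 0.343 (axially aligned).

`runSyntheticExperiment()` repeats this over many seeded pairs and
aggregates the error statistics; `registerPullbackFiles()` runs the pipeline
on TIFF/PNG pullbacks from disk, and `inst/scripts/ivusreg.R` exposes
`simulate` / `register` / `evaluate` / `experiment` subcommands for shell
use.

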