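---
title: "Predicting cell-division timing from 3D shape: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-division timing from 3D shape: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotimer)
```

## The problem

In live imaging of developing tissue, some experiments must act *before*
a tracked cell divides: labelling a mother cell, switching to high-speed
acquisition, or manipulating the cell at a defined point of its cycle.
Division is preceded by mitotic rounding — an elongated, often
teardrop-shaped cell contracts into a compact ball over the last ~40
minutes — and that geometric progression is stereotyped enough to act as
a clock. `mitotimer` estimates, at every frame, how many frames remain
until division, using nothing but the cell's binarized 3D mask.

## Shape descriptor

A mask is summarized by the central second-moment tensor of its occupied
voxel centres, computed in *physical* coordinates. This matters because
voxels are anisotropic (defaults: 0.516 µm in x/y, 0.775 µm in z, the
calibration of a typical confocal z-stack): computed in index units, the
same cell imaged at a different orientation would get different
eigenvalues, defeating the purpose of an orientation-free descriptor.

The tensor's eigenvalues, sorted descending and divided by their sum,
give `(λ̃1, λ̃2, λ̃3)` with `λ̃1 + λ̃2 + λ̃3 = 1` — invariant under
rotation, translation and uniform scaling, so only elongation survives.
`λ̃3` is redundant and dropped. The third feature is the skewness
`A = d / v^(1/3)`, where `v` is the mask volume and `d` the distance
between the centre of mass and the shape's geometric centre. Two points
about `A` deserve explanation:

* **Choice of "geometric centre".** The moment-fit ellipsoid is centred
  at the centroid by construction, so that centre cannot be used (it
  would force `d = 0` identically). We take the midpoint of the occupied
  extent along each principal axis of the moment tensor — the centre of
  the principal-frame bounding box — mapped back to world coordinates.
  For any point-symmetric solid this coincides with the centroid
  (`A = 0`); for a teardrop the centroid shifts toward the wide end and
  `A > 0`. Principal axes rather than image axes keep the quantity
  rotation-invariant.
* **Normalization by `v^(1/3)`.** `d` is a length, so dividing by the
  cube root of the volume is the only power that makes `A` dimensionless
  and hence invariant under uniform scaling.

Numerical conventions: voxel centres at `(i − 0.5) · spacing` for
1-based indices; eigenvalues from `eigen(symmetric = TRUE)` (descending
by construction, ties broken by order — no axis identity is assigned);
masks with fewer than two occupied voxels are rejected as degenerate
rather than returning an all-zero tensor.

## Image pipeline

The preprocessing chain mirrors a standard confocal workflow: 3D median
filter (spherical neighbourhood, radius 2 voxels, nearest-value edge
padding — the "radius" convention of common image-processing menus; a
cubic element is available), centre crop to a 45×45×45-voxel single-cell
ROI, fixed-threshold binarization (the threshold is chosen once per cell
on its first frame and reused for the whole series), and
largest-connected-component cleanup (26-connectivity by default) as an
automated surrogate for manual removal of neighbouring-cell fragments —
justified because the target cell dominates its ROI by construction. An
Otsu initializer is provided for convenience but is off by default; the
reference workflow is a manually chosen threshold. Note that a radius-2
median filter remodels the mask surface slightly even on noise-free
input (about 2% of voxels on a smooth phantom); exact mask recovery
holds only with smoothing disabled. Registration and cell tracking are
out of scope: input is one motion-corrected ROI series per cell.

## Reference model and inference

Time is indexed by `τ`, the number of frames before division (`τ = −1`
is the last pre-division frame; one frame = 2.5 min). From a cohort of
division-aligned trajectories the package fits, at each
`τ ∈ {−15, …, −1}`, an independent Gaussian per feature: the sample mean
and the *population* variance (denominator `n`). The population form is
chosen deliberately — at cohort size 39 the difference from `n − 1` is
immaterial, but the convention must be fixed for reproducibility.
Diagonal rather than full covariance keeps the likelihood a product of
three univariate densities and the Mahalanobis reading of the MLE
well-defined with three scale factors. The 15-frame support reflects the
empirical finding that earlier shapes are statistically
indistinguishable; frames before `τ = −15` are pooled into an
"early-phase" reference set.

Inference is a discrete Bayesian filter. At first observation the prior
is uniform, `p(τ) = 1/15`. The time evolution of the prior is the
deterministic one-frame shift: a cell at `τ` one frame ago is at `τ + 1`
now, so the step-`s` posterior, shifted by one, is the step-`s+1` prior
over the shrunken support `{s + 1 − 15, …, −1}`. Mass on `τ = −1` is
*clamped* there rather than truncated away: a cell whose posterior says
"dividing now" but which is still visible should keep that belief, and
truncation could produce an all-zero prior for a cell lingering in the
rounded state. Clamping is the only evolution rule we found consistent
with keeping the support inside `{s − 15, …, −1}` while conserving
probability mass. If the posterior sits at `τ = −1` as a point mass for
two consecutive steps, the state raises a `division_imminent` flag;
observing more than 15 frames without division is an explicit
observation-overrun error, not a silent wrap-around. All probability
arithmetic is done in log space with max-subtraction normalization —
three-feature Gaussian densities overflow/underflow quickly at small
variances — with a uniform fallback (and warning) if every likelihood
underflows.

The point estimate is the posterior mean `τ̂`, reported unrounded in
frames and minutes. Baselines: the single-frame MLE
(`argmax_τ p(f|τ)`, ties resolved toward the latest `τ`), and a k-NN
gate that votes early/late among all reference frames under Euclidean
distance on `(λ̃1, λ̃2, λ̃3, A)`. The neighbour count is not dictated by
anything in the problem; `k = 5` is the package default (odd, small
relative to the ~700-frame reference set) and is exposed in the
configuration. Tied votes resolve to "late" so that a borderline cell
stays under observation rather than being dropped.

## Synthetic data

No imaging cohort ships with the package, so the generator defines the
study conditions. `default_truth()` is a fixed, documented table: with
`u = (−τ − 1)/14`,

* `µ_λ̃1(τ) = 0.35 + 0.27 u^0.8`
* `µ_λ̃2(τ) = 0.325 − 0.085 u^0.8`
* `µ_A(τ) = 0.01 + 0.11 u`

with constant SDs (0.02, 0.015, 0.02). The `u^0.8` exponent makes the
drift accelerate toward division, as mitotic rounding does; per-frame
mean steps are of order one SD, so neighbouring frames overlap yet are
statistically distinguishable — the regime in which probabilistic
pooling over frames is genuinely needed. The stationary early phase
(`τ < −15`) sits at (0.66, 0.215, 0.16) with SDs (0.03, 0.02, 0.03):
slightly beyond the `τ = −15` distribution, so early cells look alike
but remain separable from — while overlapping with — the start of the
informative window, which is what makes the k-NN gate a meaningful test
(its synthetic error mass is a few percent, versus ~20% reported on real
cells; real cohorts are harder than this phantom world).

Trajectories draw each frame independently from the per-`τ` Gaussian;
draws outside the valid region (`λ̃1 ≥ λ̃2 ≥ 0`, `λ̃1 + λ̃2 ≤ 1`,
`A ≥ 0`) are rejected and redrawn rather than clipped, so no probability
mass piles up on the boundary. Per-cell seeds are a fixed hash of the
cohort seed and the cell index, making cell `i` reproducible regardless
of cohort size. Default cohort size is 39 cells with start frames
uniform on `{−20, …, −15}`.

Voxel phantoms are solid ellipsoids, optionally tapered linearly along
the long axis into a teardrop (taper fraction `skew ∈ [0, 1)`; `0` is a
plain ellipsoid), rotated, translated, and rasterized by the
centre-inside rule. A phantom that would be clipped by the grid is an
error, because clipping silently biases the moment tensor. The map from
feature vectors back to phantoms (semi-axes proportional to `√λ̃k`,
taper proportional to `A`) is approximate — the taper itself perturbs
the eigenvalues — and is used only to exercise the image pipeline, not
to define the truth. The generator makes no attempt at microscopy
realism: no point-spread function, no shot noise, no fluorescence
gradients; it emulates *binarized masks*, so passing tests demonstrate
the correctness of the descriptor and inference machinery, not
robustness to segmentation error on real images.

## Evaluation design

`loocv()` refits the model once per held-out cell and runs both
estimators over that cell's frames truncated to `τ ≥ −15`, recording
`τ̂` against the true `τ` at every step. Errors are `τ̂ − τ` in frames,
histogrammed on rounded integer deviations. The Bayes-vs-MLE comparison
pools absolute errors over all (cell, step) pairs into one two-sided
Mann-Whitney test — per-step pooling is available by subsetting the
records table. The rank-sum implementation uses exact enumeration when
both samples are small (`n ≤ 8`) and tie-free, and the tie- and
continuity-corrected normal approximation otherwise; the all-tied case
is degenerate and reported as `U = n1·n2/2`, `p = 1` with a warning.

One empirical subtlety: because the candidate set is truncated at
`τ = −15`, cells first observed at the boundary get *more* accurate
step-0 estimates than cells first observed mid-window (the posterior
cannot spread below −15). Accuracy as a function of start frame is
therefore not monotone at step 0; what is robust — and what the tests
assert — is that within every start group the error shrinks as the
observation progresses, and that pooled per-`τ` error decreases toward
division.

Problem sizes used throughout the tests and the acceptance script —
cohorts of 39 cells (about 600 informative frames), phantom grids of
32³–48³ voxels, five seeded LOOCV replicates for the method-ordering
check — are the scale of the imaging study the package is designed
around, and keep a full run in the minutes range on a single core.

## Known limitations

* The Gaussian per-`τ` model is fitted per feature; real features are
  correlated (e.g. `λ̃1` and `A` both track elongation), and a full
  covariance could sharpen the likelihood. Deliberately out of scope.
* The transition model is the deterministic one-frame shift; cells whose
  rounding stalls (e.g. arrested divisions) violate it and surface as
  `division_imminent` flags or overrun errors rather than re-estimated
  timing.
* The synthetic generator's independence across frames understates the
  autocorrelation of real trajectories; sequential-inference gains
  measured on synthetic cohorts are therefore an upper bound on what the
  same model achieves on real data.
* Thresholding is global per cell; photobleaching over long series can
  make a fixed threshold drift relative to the signal.
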