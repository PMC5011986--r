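# mitotimer

Predicting when a tracked cell will divide, from its 3D shape alone.

Dividing cells in live-imaged tissue go through a stereotyped *mitotic
rounding* phase: over the last half hour or so before cytokinesis an
elongated, asymmetric cell pulls itself into a compact, symmetric ball.
`mitotimer` turns that geometry into a clock. It is aimed at live-imaging
experiments — for example, tracking neural progenitors in the zebrafish
spinal cord — where an intervention (photo-labelling, laser manipulation,
high-speed acquisition) must be triggered *before* a division happens, so
the remaining time to division has to be estimated online, frame by frame,
from the image stream.

## The shape descriptor and the model

Each binarized single-cell z-stack (a voxel mask `V` with anisotropic
physical voxel spacing) is reduced to three numbers. Let `M` be the 3×3
central second-moment tensor of the occupied voxel centres in physical
coordinates,

    M_pq = (1/N) Σ_i (p_i − p̄)(q_i − q̄),   p, q ∈ {x, y, z},

with eigenvalues `λ1 ≥ λ2 ≥ λ3` (the squared principal radii of the
best-fitting ellipsoid, up to a factor). The normalized eigenvalues
`λ̃k = λk / (λ1+λ2+λ3)` are invariant under rotation, translation and
uniform scaling; a sphere sits at `(1/3, 1/3, 1/3)` and elongation pushes
`λ̃1` toward 1. Since `λ̃3 = 1 − λ̃1 − λ̃2`, only the first two are kept.
Asymmetric elongation (the typical "teardrop" of a cell anchored by a
process) is captured by the skewness

    A = d / v^(1/3),

where `d` is the distance between the mask's centre of mass and its
geometric centre (the midpoint of the occupied extent along each principal
axis) and `v` is the mask volume; `A` is dimensionless and vanishes for
point-symmetric shapes. The per-frame feature vector is
`f = (λ̃1, λ̃2, A)`.

Time is counted in frames before division: `τ = −1` is the last
pre-division frame, one frame = 2.5 min. From a training cohort of
division-aligned trajectories, the package fits an independent Gaussian
per feature at each `τ` in the informative window `τ = −15 … −1` (cell
shape carries no timing signal earlier than that; a k-NN gate screens out
such "early" cells). Prediction is sequential Bayesian inference: the
first observed frame is combined with a uniform prior `p(τ) = 1/15`; at
every subsequent frame the previous posterior, shifted one frame toward
division (with mass clamped at `τ = −1`), serves as the prior and is
multiplied by the new frame's likelihood. The reported estimate is the
posterior mean `τ̂ = Σ τ p(τ | f(0..s))`, in frames and minutes. Two
baselines are included: a single-frame maximum-likelihood estimator
(equivalently, nearest `τ` in Mahalanobis distance) and the k-NN
early/late discriminator.

No imaging dataset ships with the package; a synthetic-data module
generates cohorts with the assumed statistical structure — per-`τ`
Gaussian feature distributions drifting toward the rounded point
`(1/3, 1/3, 0)` — both directly in feature space and as rendered voxel
phantoms (tapered, rotated ellipsoids on a grid), so every stage from TIFF
reading to LOOCV is testable end to end.

## Worked example

```r
library(mitotimer)

truth  <- default_truth()                       # documented ground-truth drift
cohort <- sample_cohort(truth, n_cells = 39, seed = 1)
model  <- fit_reference_model(cohort)
model
#> <reference_model> 15 support frames (585 frames total), 101 early-phase frames, interval 2.5 min

# a newly observed cell, first seen 8 frames (20 min) before it divides
cell  <- sample_trajectory(truth, start_tau = -8, seed = 99, cell_id = "new_cell")
predict_division(cell, model)
#> # A tibble: 8 × 8
#>   cell_id   step   tau tau_hat_frames tau_hat_minutes mle_tau p_max
#> 1 new_cell     0    -8          -8.07          -20.2       -8 0.460
#> 2 new_cell     1    -7          -7.27          -18.2       -7 0.646
#> 3 new_cell     2    -6          -5.94          -14.8       -5 0.834
#> 4 new_cell     3    -5          -4.92          -12.3       -5 0.890
#> 5 new_cell     4    -4          -4.00          -10.0       -5 0.951
#> 6 new_cell     5    -3          -3.01           -7.53      -3 0.974
#> 7 new_cell     6    -2          -2.01           -5.02      -2 0.989
#> 8 new_cell     7    -1          -1.00           -2.51      -1 0.998
```

Each row is one observation step: `tau_hat_frames` is the posterior-mean
estimate of the frames remaining (so −8.07 at first sight means "about
20 minutes to division"), `mle_tau` the single-frame baseline, and `p_max`
the posterior mass on the most probable frame — watch it sharpen as
evidence accumulates. Leave-one-out cross-validation over the cohort
compares the two estimators:

```r
report <- loocv(cohort)
report
#> <loocv_report> 39 cells, 585 (cell, step) records
#>   Bayes MAE 0.213 frames | MLE MAE 0.692 frames | rank-sum p = 1.41e-05
autoplot(report)                 # per-tau predictions vs truth
plot_error_histogram(report)     # frame-deviation histogram by method
```

The sequential estimator's mean absolute error (0.21 frames ≈ 0.5 min) is
about a third of the stateless MLE's, and the Mann-Whitney rank-sum test
on the pooled absolute errors confirms the ordering.

For image input, `extract_features_file()` (or the `mitotimer extract`
subcommand of `inst/scripts/mitotimer`) runs the acquisition pipeline —
3D median filter, 45×45×45 ROI crop, threshold binarization,
largest-component cleanup — and `cmd_watch()` polls a folder for newly
written `<cell_id>_t<frame>.tif` stacks, gates first frames through the
k-NN early/late vote, and emits `τ̂` per frame in real time with per-cell
state persisted across restarts.

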