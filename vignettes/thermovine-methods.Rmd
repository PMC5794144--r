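---
title: "Methods: estimating grapevine stem water potential from on-the-go thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating grapevine stem water potential from on-the-go thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermovine)
```

## The problem

Midday stem water potential ($\Psi_{stem}$, MPa, negative) is the reference
measure of grapevine water status, but it is destructive and slow: a
pressure chamber, a bagged dark-adapted leaf, one vine at a time. Canopy
temperature is a fast proxy — stomatal closure under water stress suppresses
transpirational cooling, so stressed canopies run warmer relative to the
evaporative limits of their environment. `thermovine` implements a complete
pipeline for estimating $\Psi_{stem}$ from thermal video recorded by a
camera moving along the row on a vehicle ("on-the-go" sensing), together
with a synthetic vineyard campaign generator so that every stage is testable
without field data.

The pipeline has five stages, each an independent module:

1. **synth** — generate weather, wet/dry reference temperatures, ground-truth
   $\Psi_{stem}$, and thermal frames with sky/canopy/soil structure;
2. **geometry** — acquisition arithmetic: ground coverage per frame, frame
   counts, the non-overlap subsampling stride, middle-frame selection;
3. **thermal** — ROI cropping, reference-range segmentation, per-frame
   statistics and the CWSI / $I_g$ indices;
4. **forest** — a from-scratch rotation-forest regressor over
   reduced-error-pruning (REP) trees;
5. **evaluate** — the calibration / 10-fold cross-validation / external
   prediction protocol with range-and-date-stratified splitting and a
   slope-equality test between canopy-side models.

## Thermal indices

With $T_{wet}$ and $T_{dry}$ the temperatures of a continuously wetted and a
dry artificial reference leaf (an evaposensor), and $T_{canopy}$ the mean
temperature of the canopy region of interest:

$$\mathrm{CWSI} = \frac{T_{canopy} - T_{wet}}{T_{dry} - T_{wet}}, \qquad
I_g = \frac{T_{dry} - T_{canopy}}{T_{canopy} - T_{wet}}.$$

CWSI is 0 at full transpiration and 1 at none; $I_g$ is proportional to
stomatal conductance and satisfies $I_g = 1/\mathrm{CWSI} - 1$ wherever both
are defined. The segmentation interval $[T_{wet}, T_{dry}]$ is **closed at
both ends** so that reference-equal pixels survive and the index boundaries
0 and 1 remain attainable. $I_g$ is undefined at $T_{canopy} = T_{wet}$
(non-transpiration-limited edge); the package raises an error there rather
than returning an infinity.

## Acquisition geometry

A camera with fields of view $\phi_h \times \phi_v$ at distance $d$ covers a
scene of $2d\tan(\phi_h/2) \times 2d\tan(\phi_v/2)$. At the defaults
(48° × 39°, 1.2 m) that is 1.07 m × 0.85 m. Driving a 25 m replication at
5 km/h while recording at 60 FPS yields 1080 frames; since each frame spans
1.07 m, only one frame in 46 shows a laterally disjoint scene, giving 23
non-overlapping frames, of which the centred 14 cover the monitored middle
15 plants.

These counts mix rounded intermediates (25/1.07 = 23.36), so the rounding
contract matters and is frozen as follows: frame counts and the stride use
round-half-away-from-zero, the retained middle-block size uses `floor`
(`floor(15 / 1.07) = 14`). When the number of frames to drop from the
subsample is odd, the extra frame is dropped at the end of travel. Frame
indices are 0-based everywhere in the package.

## The synthetic campaign: a stated world

The generator emulates a campaign of 7 weekly dates × 3 irrigation regimes
(T0 full, T1 moderate, T2 none) × 4 blocks × 2 canopy sides, with 3 measured
vines per replication: 36 measurements/day, 252 per side. Its target
marginal distribution of $\Psi_{stem}$ is mean −1.23 MPa, SD 0.298 MPa,
range [−2.05, −0.40] MPa.

The generative model is deliberately the simplest monotone link consistent
with the premise that canopy temperature tracks water status:

$$\Psi_{stem} = a + b \cdot \mathrm{CWSI}^{true} + s + \varepsilon,$$

with $a = -0.40$, $b = -1.65$ (so the index range $[0,1]$ maps onto the
observed $\Psi_{stem}$ range), $s = \pm 0.01$ MPa a canopy-side effect,
and $\varepsilon \sim N(0, 0.16^2)$ by default. Draws are clamped to the
configured range (clamping probability < 1% at the defaults; its effect on
the marginal mean is well below the 0.02 MPa calibration tolerance). The
latent index is Beta-distributed with precision 30; treatment means are
spread ±0.14 around the centre implied by the target mean
($(\!-1.23 + 0.40)/(-1.65) \approx 0.503$), and the unirrigated regime
drifts drier over the season (slope 0.2 over the centred date covariate).
With these defaults the marginal SD of $\Psi_{stem}$ works out to ≈0.30
MPa. Weather (air temperature ~N(30, 3) °C, relative humidity ~N(40, 8) %
clamped to [15, 80], irradiance ~N(850, 80) W/m²) and reference offsets
($T_{wet} \approx T_{air} - 3$, $T_{dry} \approx T_{air} + 6$) describe a
hot, dry mid-summer at solar noon; VPD uses the Tetens saturation pressure
(constants 0.6108 kPa, 17.27, 237.3 °C).

Rendered frames have three horizontal bands — sky at $T_{wet} - 10$ °C,
canopy at $T_{wet} + \mathrm{CWSI}^{true}(T_{dry} - T_{wet})$, soil/fruit
zone at $T_{dry} + 5$ °C, occupying 25/50/25 % of image height — plus
i.i.d. Gaussian pixel noise (SD 0.8 °C). The bands guarantee segmentation
has something to remove: the default centred 135-row ROI of a 256-row frame
(rows 61–195) overlaps the sky band by 4 rows and the soil band by 3, so
the unsegmented ("without references") feature set is mildly contaminated,
as in real frames. None of the sky/soil temperatures or the texture model
are inferred from data; they are declared defaults.

What the generator does **not** emulate: radiometric physics (emissivity,
reflected temperature, atmospheric attenuation), leaf-scale texture, shadows,
ego-motion blur, or any mechanistic link from irrigation dose to stomatal
conductance. A green test therefore establishes that the *pipeline
arithmetic and learning machinery* recover a planted signal of the assumed
form — not that the method would attain any particular accuracy on real
vineyard imagery.

### Seeding

All randomness flows from one master integer seed through named substreams
(`weather`, `truth`, `pixels` per frame index, fold and split streams).
Consequences used by the code and the tests: identical seeds give
bit-identical campaigns and reports, and rendering a *subset* of frame
indices is bit-identical to slicing a full render — the end-to-end run
renders only the 14 selected frames per replication instead of 1080.

## Feature extraction

Two feature sets mirror the two modelling approaches:

* **with_refs** (6 predictors): air temperature; mean, median, SD of the
  ROI after removing all pixels outside $[T_{wet}, T_{dry}]$; CWSI and
  $I_g$ computed from the segmented mean.
* **without_refs** (4 predictors): air temperature; mean, median, SD of the
  raw ROI. Reference temperatures are never touched at any stage.

The 14 retained frames of a replication are partitioned into 3 contiguous
groups (sizes 5/4/5, mirroring the three groups of five monitored plants);
a vine's features are the **mean of its group's per-frame statistics**.
Whether per-vine statistics should be computed per frame and then averaged,
or pooled over the pixels of all frames, is a genuinely open choice; the
per-frame-then-average rule is frozen here. Masked
pixels are carried as `NA`, never as sentinel temperatures; a vine whose
frames all segment to empty is dropped with a warning, not silently imputed.

## The learner

The regressor is a rotation forest over REP trees, both implemented from
scratch in R:

* **REP tree** — a binary regression tree grown greedily by variance
  reduction (ties broken to the lowest feature index, then the lowest
  threshold, so fits are reproducible), with at least 2 instances per leaf
  and no depth limit. Rows are split into 3 internal folds; the tree is
  grown on two and pruned bottom-up against the third: a split collapses
  whenever the pruning-fold squared error does not increase. After pruning,
  the pruning fold is passed back down and leaf means are re-estimated from
  the combined data (backfitting). A node whose target variance falls below
  $10^{-3}$ of the root variance is not split. These defaults mirror the
  widely used Weka implementation of the same learner.
* **Rotation forest** — 10 trees. For each tree the features are randomly
  partitioned into groups of ≤ 3; per group, principal axes are estimated
  (via the eigendecomposition of the covariance, all axes retained,
  centring vector stored) on a 75% bootstrap row sample; the block-diagonal
  rotation is applied to *all* rows and one REP tree is trained on the
  rotated data. Predictions are the per-tree mean; the per-row SD across
  trees is attached as an attribute. The class-conditional subsampling of
  the original classification formulation has no regression analogue, so
  rows for axis estimation are drawn by plain bootstrap. Zero-variance
  groups fall back to identity axes with a logged message. Eigenvector signs
  are normalised (largest-magnitude loading positive) for cross-platform
  determinism.

Field studies pairing these two learners rarely report hyperparameters
beyond the learner names, so only protocol parity — not numeric parity with
any particular field result — is claimed (see limitations).

## Evaluation protocol

Side-specific datasets (252 records each) and a **global** dataset are
evaluated. The global set takes half of every (side × regime × date) cell
pseudorandomly — 6 of 12 records per cell, 126 per side — so both sides,
all regimes and all dates are equally represented.

The 80/20 split is "not totally random": the records holding the global
minimum and maximum $\Psi_{stem}$ are forced into the test set, and the
remaining test slots are filled with equal per-date quotas (remainders
assigned in seeded date order). 252 records cannot split 80/20 into whole
numbers, so when $1/(1-\mathrm{ratio})$ is a
whole number $k$, $n \bmod k$ records are excluded from both sets at random
(seeded and recorded in the split plan) — 2 records at the defaults, leaving the
conventional 200 train / 50 test shape. The exclusion is recorded in the
split plan rather than silently resolved.

Three figures of merit per dataset and feature set: **calibration** (fit on
train, evaluate on train), **cross-validation** (10 seeded folds within
train, held-out predictions pooled before computing metrics), and
**prediction** (fit on train, evaluate on the held-out test). $R^2$ is the
squared Pearson correlation between observed and predicted — matching the
observed-vs-predicted regression-plot convention — with the
coefficient-of-determination variant ($1 - SSE/SST$) reported alongside,
since both conventions circulate in this literature. RMSE is in MPa. Equality of the east/west calibration lines is tested by comparing the
slopes of the observed-on-predicted regressions with a pooled-residual
t statistic on $n_1 + n_2 - 4$ degrees of freedom.

## Numerical and design choices

* Rounding: half-away-from-zero for frame counts (base R's `round()` would
  give banker's rounding); `floor` for the middle block.
* The split's excluded-record rule generalises the 252 → 200/50 adjustment
  to any ratio with integral $1/(1-\mathrm{ratio})$.
* CV folds are a seeded random partition of the train set without further
  stratification.
* Degenerate inputs fail loudly: $T_{dry} \le T_{wet}$, empty segmentations,
  out-of-bounds ROIs, zero predictor variance in the slope test, unknown
  config keys.
* Frames are stored as plain CSV matrices; no TIFF writer is available in
  the supported dependency set, and the CSV path keeps fixtures
  text-only and inspectable.

## What the acceptance surface establishes

The self-contained worked arithmetic (coverage 1.07/0.85 m, 1080 frames,
stride 46, 23 subsampled, 14 retained, 36/day, 252/side) is recomputed
exactly. The generator's calibration is checked by Monte Carlo (500 seeds,
grand mean within ±0.02 MPa of −1.23). Learner correctness is checked
against an exhaustive best-split oracle on tiny tables, orthonormality of
all stored rotations, a collapse case (1 tree, identity rotation ⇒ plain
tree), and the pruning monotonicity guarantee. Signal recovery — the
pipeline attaining 10-fold CV $R^2 \ge 0.8$ on campaigns where
$\Psi_{stem} = -0.40 - 1.65\,\mathrm{CWSI} + N(0, 0.1^2)$ — is a stochastic
quantity (measured SD ≈ 0.02 across campaign seeds, against a
seed-dependent oracle ceiling of 0.83–0.88); it is therefore evaluated as
the mean over five consecutive campaign seeds rather than a single draw.
Field studies of this workflow report cross-validated $R^2$ around 0.6 on
real vineyard data; such values are **not** reproduction targets here — no
real field data are bundled, and the synthetic world is not a radiometric
simulation.

## Known limitations

* The $\Psi_{stem}$–CWSI link is linear by construction; the pipeline's
  recovery results say nothing about non-linear stomatal behaviour.
* Per-frame statistics are aggregated per vine by unweighted means; group
  sizes 5/4/5 make the middle vine's estimate slightly noisier.
* The rotation forest exposes per-tree usage only through the stored
  groups; no variable-importance measure is provided.
* `Ig` is numerically fragile near $T_{canopy} = T_{wet}$; models built on
  near-saturated canopies should prefer the with-refs mean or CWSI.
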