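---
title: "Segmenting dual-contrast thigh MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting dual-contrast thigh MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Severe spinal cord injury causes thigh muscle atrophy and infiltration of
adipose tissue between the muscles. Quantifying these changes from MRI —
volumes of subcutaneous fat (SAT), intermuscular fat (IMAT), total muscle,
and the functionally distinct muscle groups (knee extensors, knee flexors,
and the medial compartment holding sartorius, gracilis and the adductors) —
is laborious to do by hand. `thighseg` implements a fully automatic
stochastic pipeline for this task, working from a pair of co-registered
volumes per subject: a fat-suppressed (FS) acquisition in which muscle is
bright and fat dark, and a water-suppressed (WS) acquisition with the
opposite contrast. The pipeline has four stages:

1. **Tissue extraction.** Two-class intensity splits of the FS + WS sum
   (whole thigh and bone), the FS volume (muscle) and the WS volume (fat),
   with the muscle mask overlaid on the fat mask to split SAT from IMAT.
2. **Atlas registration.** Nonrigid B-spline free-form-deformation alignment
   of gated atlas subjects to the target.
3. **Joint Markov–Gibbs random field (MGRF) segmentation** of the muscle
   into three compartments, fusing an atlas shape prior, a Potts spatial
   model and per-group intensity models through iterated conditional modes
   (ICM).
4. **Quantification** of tissue volumes by voxel counting, with Dice,
   precision, recall and Hausdorff metrics for validation.

## The LCDG intensity model

Each two-class split starts from the empirical distribution of Q = 256 gray
levels (volumes are affinely rescaled so the minimum maps to level 0 and the
maximum to Q − 1, half-up rounding). The distribution is modelled by a
*linear combination of discrete Gaussians* (LCDG): two dominant DGs — a
plain non-negative mixture capturing the bimodal dark/light structure —
plus 4 additive and 4 subtractive subordinate DGs that absorb the positive
and negative parts of the deviation between the empirical distribution and
the dominant fit. A discrete Gaussian assigns each level the Gaussian mass
of its unit bin, with the end bins absorbing the tails, so every component
sums to exactly one.

The estimation details are fixed as follows:

* the dominant pair is fitted by deterministic EM on the histogram,
  initialised from weighted quantiles (200 iterations, tolerance 1e-8 on
  the weighted log-likelihood);
* the positive / negative deviation parts are each fitted by a small EM of
  the configured order; component sigmas are floored at 0.5 gray levels so
  single-level spikes cannot collapse them;
* all signed weights are then re-fitted jointly by least squares with the
  component shapes held fixed, the refit being kept only while the L1 error
  against the empirical distribution does not increase — so the final model
  is never worse (in L1) than the dominant-only fit, and the recorded L1
  trace is non-increasing by construction;
* components with |weight| < 1e-4 are pruned when doing so respects the
  same L1 guarantee;
* the evaluated total density is clipped at zero and renormalised, making
  it a proper distribution.

Class posteriors P1 (dark) and P2 (light) are the responsibilities of the
two dominant modes, computed in log space so the far tails never underflow
to an indeterminate 0/0; they are monotone for ordered modes, and the
conditional class densities are the responsibility-partitioned total
density. The binarisation threshold is the smallest level with P2 ≥ P1
(ties to the light class), and thresholding at it is exactly equivalent to
the per-level posterior rule. On two-Gaussian simulations spanning mode
separations from 136 down to 36 levels (sigma 12, 1e5 draws) the recovered
threshold sits within ±5 levels of the brute-force Bayes-optimal threshold.

### Masking convention

The FS and WS histograms are computed within the thigh mask; the FS + WS
histogram uses the full volume (there is no thigh mask yet at that stage).

## Tissue composition rules

* **Thigh**: largest 26-connected light component of the binarised FS + WS
  volume, holes filled. Hole filling is done slice-wise in 2-D (4-connected
  background flood per axial slice): a cortical-bone tube spanning the full
  slab is open at both z-ends, so a 3-D flood would never classify the ring
  interior as a hole.
* **Bone**: dark components of the FS + WS split that lie strictly inside
  the thigh (no voxel 26-adjacent to non-thigh) are cortical bone; the
  cavity they enclose (slice-wise fill minus the ring) is marrow; the bone
  mask is their union after morphological closing with a 3-voxel ball.
  Components below 100 voxels are ignored as speckle.
* **Muscle**: light FS class within the thigh, minus bone.
* **SAT / IMAT**: light WS class within the thigh (minus bone and muscle)
  is total fat; the *muscle envelope* — the muscle mask closed with a
  5-voxel ball and hole-filled, a proxy for the fascia lata — splits it
  into IMAT (inside) and SAT (outside). Fat between fascia and muscle
  envelope therefore counts as IMAT; this is the operative definition.

Erosion treats out-of-volume voxels as foreground so closing does not eat
structures that extend through the slab ends.

## B-spline registration

Atlases are aligned to the target by a free-form deformation: a uniform
cubic-B-spline control grid (spacing 8 voxels, one boundary ring) whose
control displacements define a dense displacement field. The dissimilarity
is the mean sum of absolute differences (SAD) between the target and the
trilinearly warped source. The optimiser is deterministic discrete ICM over
the control points in raster order: candidate moves `current + step *
{-1, 0, 1}^3` voxels, step sizes 4 → 2 → 1 (two passes each), scored by the
B-spline-support-weighted local SAD plus a first-order smoothness penalty
λ Σ ||Δζi − Δζj|| over 6-neighbour control pairs with λ = 0.1; strict
improvement is required to move. Because the sum of the support-weighted
local energies telescopes to the global SAD (the B-spline weights partition
unity), every accepted move decreases the global objective, and a final
guard returns the identity transform in the degenerate case that the
optimum scored worse than it (so the returned energy never exceeds the
identity energy). A centre-of-mass pre-alignment (a uniform control shift)
is applied first and kept only if it helps.

Two approximations keep a registration at the default 96×96×50 grid around
ten seconds on one CPU: candidate scoring samples the support with a fixed
stride (4/3/2 voxels at steps 4/2/1) and restricts itself to the inner 1.5
cells of the 2-cell support; accepted moves always update the dense field
over the full support. A single fixed control grid with shrinking step
sizes (rather than an image/grid pyramid) keeps the invariant that the
returned dense field is exactly the B-spline expansion of its control grid.

On a phantom warped by a known smooth field of 4-voxel peak amplitude the
optimiser recovers the field to ≈1.3 voxels mean end-point error inside the
thigh and reaches about a third of the identity energy. The residual error
concentrates in the flat muscle interior where SAD carries no signal (the
aperture problem); the smoothness term interpolates those regions.

## Atlas gating and the shape prior

Candidate atlases are screened by the mean over axial slices of the 2-D
Pearson correlation with the target (computed on rescaled intensities; a
zero-variance slice contributes r = 0); an atlas is used iff the mean
correlation is ≥ 0.5. Selected atlases are registered to the target and
their 4-label ground-truth maps transported by nearest-neighbour warping
(no partial-volume voting, for determinism). The shape prior at voxel v is
the Laplace-smoothed vote fraction

  p(v, l) = (count_l(v) + α) / (n_selected + α L),  α = 0.5,

so no voxel–label pair is ever exactly impossible and the intensity and
spatial terms can override a unanimous-but-wrong vote. The prior is
restricted to the muscle mask from stage 1 — outside it the background
label has probability one — because muscle extraction precedes compartment
labelling in the pipeline.

## The Potts spatial model

Spatial homogeneity is modelled by a pairwise Potts MGRF on the
26-neighbourhood with bi-valued potentials (v_eq for equal neighbouring
labels, v_ne = −v_eq otherwise). The maximum-likelihood potential estimate
is analytic: v_eq = 2 f_eq − 1, where f_eq is the relative frequency of
equal labels over unordered neighbour pairs; pairs crossing the volume (or
domain-mask) boundary are excluded, which avoids bias from artificial
border labels. The partition function is never evaluated — only voxel-wise
conditionals, which need local normalisation, are used.

## Fusion by ICM

The joint model factorises as P(g, m) = P(g|m) · P_sp(m) · P_V(m): the
per-label intensity densities, the shape prior and the Potts conditionals
are combined as a plain product (equal exponents by default; configurable).
Per-label intensity densities are LCDGs with 2 dominant + 2 additive + 2
subtractive DGs — smaller than the global 2/4/4 because each muscle group
is near-unimodal and small classes need the stability.

The initial map assigns every muscle-mask voxel the label maximising
prior × intensity (intensity models bootstrapped from the prior's argmax
labelling). Refinement sweeps then repeat: re-estimate v_eq from the
current map, re-fit the per-label densities (an emptied label keeps its
previous density, flagged), and reassign voxels in fixed raster order to
the conditional argmax, ties to the lowest label id. Sweeps stop when fewer
than 1e-4 of the mask voxels change, or after 20 sweeps.

The Potts conditional used in the sweep counts only neighbours *inside*
the domain mask, consistent with the potential estimator. Counting frozen
out-of-mask background neighbours instead would systematically erode the
mask rim toward background during refinement; with the consistent
restriction, refinement improves on the initial map. Under frozen models
each reassignment increases the joint objective Σ log(p_sp · p_V · p_int),
so the recorded objective trace is non-decreasing — with model
re-estimation between sweeps this strict guarantee no longer holds, which
is why the `freeze_models` switch exists.

IMAT voxels inside the muscle envelope are excluded from group labelling
(the groups are muscle tissue only); `assign_imat_to_groups()` optionally
attaches each IMAT voxel to its nearest labelled group afterwards for
compartment-with-IMAT volume reporting.

## Accuracy metrics

Dice = 2TP / (FP + 2TP + FN), precision = TP / (TP + FP) and recall =
TP / (TP + FN) are computed from voxel-wise confusion counts over the full
grid. The Hausdorff distance is the symmetric max-min distance between the
two boundary voxel sets in physical millimetres (a boundary voxel is a
positive voxel with a 6-connected negative neighbour or on the grid edge).
Degenerate cases are explicit: both masks empty gives Dice 1 and HD 0 with
a warning; exactly one empty gives Dice 0 and an HD error naming the empty
side. Volumes are voxel count × voxel volume, reported in mm³ and mL.

## The synthetic phantom

No imaging data ships with the package; every validation runs on a
parametric dual-contrast phantom with known ground truth. It emulates an
axial thigh slab as a cylinder: a subcutaneous fat ring, a muscle annulus
crossed by thin radial IMAT streaks, an off-centre cortical bone ring with
a bright (fatty) marrow core, and three angular compartments standing in
for extensors, flexors and the medial group. Defaults mirror the intended
acquisition scale at desk size: a 96 × 96 × 50 grid at 1.5 mm isotropic
voxels (a 50-slice mid-thigh slab), FS levels background 5 / fat 60 /
cortical 20 / marrow 180 / muscle 190 on a 0–255 scale with fat and muscle
swapped on WS, and Gaussian noise with σ = 5% of the dynamic range. Atlas
families apply an independent smooth random B-spline warp per member
(control spacing 16 voxels, amplitude set by `jitter_mm`, default study
condition 3 mm) to the volumes and the truth jointly, then add noise, so
atlas truth stays consistent with atlas images.

What the phantom does *not* emulate — anatomically shaped muscles, bias
fields, partial-volume fading, through-slice geometry changes — bounds what
green tests mean: they validate the estimators and the pipeline logic under
controlled conditions, not clinical-grade accuracy on real scans. On real
data the contrast between tissues is weaker and the fascia is not a clean
morphological envelope, so accuracy will be lower than the near-perfect
phantom numbers.

Problem sizes used in the shipped validation: default-size phantoms for
the tissue, registration and leave-one-out studies (six-member family,
leave-one-out over all six folds); 64 × 64 × 20 phantoms for unit tests;
20 seeded histogram simulations of 1e5 draws for threshold recovery.

## Other choices and limitations

* Bias-field correction is not implemented; inputs are assumed corrected
  upstream (e.g. by N4), and the CLI documents this.
* The paper-scale pipeline crops a configured slice range and side rather
  than detecting anatomical landmarks; resizing after cropping is not
  performed (native resolution is preserved).
* One atlas subject can be designated the common reference via
  configuration; by default each target is its own reference.
* Determinism is a design requirement throughout: fixed raster orders,
  strict-improvement acceptance, explicit tie-breaks (lowest label id),
  and seed-derived randomness only in the phantom generator.
* `prior_log_prob` returns −Inf (flagged) for a zero-probability
  assignment, which can only occur with α = 0.
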