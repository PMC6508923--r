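# thighseg

Automatic segmentation and quantification of thigh tissues from paired
fat-suppressed (FS) and water-suppressed (WS) MRI volumes.

Severe spinal cord injury causes thigh muscle atrophy and infiltration of
ectopic adipose tissue, both of which matter clinically and functionally.
Tracking them requires separating subcutaneous adipose tissue (SAT),
intermuscular adipose tissue (IMAT), bone and total muscle, and splitting
the muscle into its functional compartments — knee extensors, knee flexors
and the medial compartment (sartorius, gracilis, adductors). Doing this by
hand is slow and rater-dependent; `thighseg` does it automatically from the
two complementary contrasts (fat is dark on FS and bright on WS; muscle the
reverse).

## Method

**Tissue extraction.** Gray-level distributions are modelled by a *linear
combination of discrete Gaussians* (LCDG): two dominant DGs fitted by EM to
the bimodal empirical distribution of Q = 256 levels, plus 4 additive and 4
subtractive subordinate DGs absorbing the deviations, refined under a
monotone L1 guarantee. The model yields per-level class posteriors
P1 (dark) and P2 (light) and a binary threshold. Thresholding FS + WS gives
the whole-thigh mask and the bone; FS gives muscle; WS gives fat, which the
muscle envelope splits into SAT and IMAT.

**Muscle-group segmentation.** A joint Markov–Gibbs random field over the
region map **m** given the gray volume **g**,

    P(g, m) = P(g | m) · P_sp(m) · P_V(m),

fuses (i) an atlas-based shape prior `P_sp(m) = ∏ p_sp:x,y,z(m_x,y,z)`
built by registering gated atlases (mean slice correlation ≥ 0.5) to the
target with cubic-B-spline free-form deformations minimising the sum of
absolute differences, (ii) a second-order Potts model on the
26-neighbourhood with analytic potentials `v_eq = −v_ne ≈ 2 f_eq(m) − 1`,
and (iii) per-group LCDG intensity densities `P(g | m)`. The map is
optimised by iterated conditional modes (ICM), re-estimating potentials and
class densities each sweep.

**Evaluation and quantification.** Dice `DC = 2TP / (FP + 2TP + FN)`,
precision, recall, the symmetric boundary Hausdorff distance in mm, and
tissue volumes by voxel counting.

All validation runs on a parametric dual-contrast thigh phantom with known
ground truth (concentric SAT ring, muscle annulus with radial IMAT streaks,
cortical bone with marrow, three angular compartments) — see the methods
vignette (`vignettes/thighseg-methods.Rmd`) for the models, parameter
defaults and design choices.

## Worked example

Leave-one-out segmentation of a six-member synthetic atlas family with 3 mm
boundary jitter and 5 % noise:

```r
library(thighseg)

spec    <- phantom_spec(jitter_mm = 3, seed = 11)
family  <- make_atlas_family(spec, n = 6)
target  <- family[[1]]
atlases <- lapply(family[-1], function(p)
  list(volume = p$fs, labels = p$truth_groups))

fit <- segment_groups(target$fs, target$ws, atlases)

fit$tissues
#> <tissue_masks> voxel counts:
#>  thigh   bone muscle    sat   imat
#> 255044  11132 170095  67689   6128

volume_ml(fit$tissues$muscle)$ml
#> [1] 574.0706

fit$result
#> <segmentation_result> 4 sweep(s), converged
#>   sweep changes      v_eq objective
#> 1     1    2342 0.9535512   1250710
#> 2     2     135 0.9758036   1296608
#> 3     3      22 0.9761275   1297329
#> 4     4      16 0.9761668   1297459

evaluate_labels(fit$result$map, target$truth_groups)
#>   label      dice precision    recall hausdorff_mm
#> 1     1 0.9915289 0.9941177 0.9889536     3.354102
#> 2     2 0.9738676 0.9845262 0.9634373     6.184658
#> 3     3 0.9865751 0.9751490 0.9982722     6.184658
```

Reading: the first stage recovered 170,095 muscle voxels (574 mL at 1.5 mm
isotropic voxels); ICM converged in four sweeps with the Potts potential
settling at v_eq ≈ 0.98 and a monotonically increasing objective; the three
muscle groups (1 = extensor, 2 = flexor, 3 = medial) reach Dice 0.97–0.99
against the held-out ground truth with boundary Hausdorff distances of
3.4–6.2 mm.

A thin command-line front-end wraps the same functions:

```sh
exec/thighseg phantom  --out data --n 6 --jitter 3
exec/thighseg tissues  --fs data/case01_fs.nii.gz --ws data/case01_ws.nii.gz --out tis
exec/thighseg segment  --fs data/case01_fs.nii.gz --ws data/case01_ws.nii.gz \
                       --atlas-dir atlases --out seg
exec/thighseg evaluate --pred seg/muscle_groups.nii.gz \
                       --truth data/case01_groups.nii.gz --out report.json
```

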