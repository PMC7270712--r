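# rodentmri

Preprocessing for small-animal (rodent and other small-mammal) brain MRI,
implemented natively in R and validated end-to-end on synthetic head
phantoms with known ground truth. The package is aimed at preclinical
imaging groups who need a scriptable, dependency-light pipeline from raw
anatomical / BOLD / ASL volumes in NIfTI-1 to template-space analysis:

* **bias-field correction** — multiplicative intensity non-uniformity
  modelled as `exp(P(x))` with a low-order polynomial `P`, fitted on a
  single reference tissue class so anatomy is not absorbed into the field;
* **brain extraction** — histogram-valley thresholding plus morphology,
  with a five-measure **mask-quality report** (volume, right-left /
  anteroposterior / inferior-superior extents, and the Pearson correlation
  between the mask and its reflection across the estimated mid-sagittal
  plane) for screening thresholds numerically;
* **registration** — rigid (6), affine (12) and multi-level nonlinear
  free-form deformation, driven by normalised mutual information
  `NMI = (H(A)+H(B)) / H(A,B)` over a multiresolution pyramid with a
  Powell direction-set optimiser; displacement fields are cubic-B-spline
  lattices with control displacements capped at 0.4 x spacing, so every
  emitted field is a diffeomorphism (discrete Jacobian verified > 0);
* **group templates** — the iterative scheme: centroid-aligned average,
  then register-all/re-average while increasing degrees of freedom
  (rigid, affine, nonlinear), with a per-iteration convergence log;
* **EPI handling** — slice-timing correction, rigid realignment to the
  first volume, temporal mean, per-slice in-plane nonlinear registration
  of EPI to the anatomy (distortion correction), and one-big-step
  composition of all transforms so data are interpolated exactly once;
* **FAIR ASL quantification** — per-voxel magnitude inversion-recovery
  fitting `S(TI) = |M0 (1 - 2 a exp(-TI/T1))|` of the selective and
  nonselective series, and cerebral blood flow by the difference of
  apparent relaxation rates, `CBF = 6000 lambda (1/T1_sel - 1/T1_ns)`
  in ml/100g/min;
* **evaluation** — Dice overlap `2|A n B| / (|A|+|B|)` for masks and
  per-region label maps;
* **phantom generator** — deterministic, seeded synthetic heads (bright
  skull shell, textured brain, ventricles) with known bias fields,
  deformations, motion and perfusion parameters, so every stage above can
  be tested against ground truth without any external dataset.

The methods vignette (`vignettes/rodentmri-methods.Rmd`) documents every
model, parameter and numerical choice in detail.

## Worked example

```r
library(rodentmri)

## a synthetic head with known ground truth, corrupted by a smooth
## multiplicative bias field
spec <- phantom_spec(seed = 42)
phantom <- make_head_phantom(spec)
field <- make_bias_field(spec, amplitude = 0.3)
scan <- volume_image(phantom$image$data * field$data, phantom$image$affine)

## bias correction
bias <- correct_bias(scan)
hm <- bias$head_mask$data == 1
resid <- log(bias$field$data[hm] / field$data[hm])
resid <- resid - mean(resid)
cat(sprintf("RMS log-bias: %.4f before, %.4f after correction\n",
            sqrt(mean(log(field$data[hm])^2)), sqrt(mean(resid^2))))
#> RMS log-bias: 0.0591 before, 0.0003 after correction

## brain extraction and mask quality
mask <- extract_brain(bias$corrected)
cat(sprintf("brain mask Dice vs ground truth: %.3f\n",
            dice(mask, phantom$truth$brain_mask)))
#> brain mask Dice vs ground truth: 1.000
print(brain_segmentation_report(bias$corrected, c(0.2, 0.35, 0.5)),
      digits = 3)
#>   threshold volume_mm3 ap_mm rl_mm is_mm symmetry_r
#> 1      0.20        269   9.6   8.4     6          1
#> 2      0.35        269   9.6   8.4     6          1
#> 3      0.50        168  12.4  11.2     9          1

## recover a known rigid displacement
moved <- apply_known_transform(bias$corrected,
                               rigid_transform(c(0, 0, 6, 0.8, -0.4, 0.5)),
                               phantom$truth)
est <- register_rigid(bias$corrected, moved$image)
#> recovered rotation: 6.08 deg (applied 6.00)

## FAIR perfusion: uniform T1 pair with known CBF
sh <- grid_shape(phantom$image)
brain <- phantom$truth$brain_mask$data
t1_ns  <- volume_image(array(1.5  * brain, dim = sh), scan$affine)
t1_sel <- volume_image(array(1.35 * brain, dim = sh), scan$affine)
m0     <- volume_image(array(1000 * brain, dim = sh), scan$affine)
tis <- c(0.05, 0.1, 0.3, 0.6, 1, 1.7, 2.6, 5)
fair <- simulate_fair_series(t1_sel, t1_ns, m0, tis,
                             noise_sigma = 20, seed = 7)
cbf <- compute_cbf(fit_inversion_recovery(fair$selective),
                   fit_inversion_recovery(fair$nonselective))
cat(sprintf("median CBF: %.0f ml/100g/min (analytic: 400)\n",
            median(cbf$data[cbf$fit_mask$data == 1])))
#> median CBF: 396 ml/100g/min (analytic: 400)
```

Reading the report: at low thresholds the mask is the brain (269 mm^3,
extents matching the 8.4 x 9.6 x 6.4 mm brain ellipsoid, symmetry 1); at
0.5 the threshold has climbed past the brain interior and the extracted
component is the skull shell — visible at a glance as a smaller volume
with *larger* extents. That screening is exactly what the report is for.

The bias range printed by `correct_bias` is over the head mask; the Dice
of 1.000 is against the generator's ground-truth brain mask; and the CBF
value is the median over the fitted brain at an SNR of 50, to be compared
with the analytic `6000 * 0.9 * (1/1.35 - 1/1.5) = 400`.

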