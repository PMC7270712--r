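---
title: "Methods: models, parameters and design choices in rodentmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in rodentmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rodentmri is a self-contained preprocessing toolkit for small-animal brain
MRI. This vignette documents the models behind each stage, the parameters
that matter (with units and defaults), the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## Image model and geometry

Every image is a dense array plus a 4x4 affine mapping **0-based** voxel
indices to world millimetres. After `reorient_to_ras()` the world frame is
RAS+ (+x right, +y anterior, +z superior). Reorientation is a pure
permutation/flip relabelling — the closest axis alignment is chosen by a
greedy assignment on the direction cosines, data are permuted accordingly,
and the affine is updated so that the world position of every piece of
tissue is unchanged; oblique affines stay oblique with a warning. No
resampling occurs, so the operation is lossless and idempotent.

`resample()` is pull-back resampling: a transform maps *reference* world
coordinates into *source* world coordinates and the source is interpolated
once (trilinear, or nearest for masks and label maps; points outside the
field of view yield 0). All composite operations — transform chains, the
one-big-step application — reduce to a single interpolation through the
composed point mapping, which is why chained application is bit-identical
to `apply_chain()` of the concatenated chain and strictly more accurate
than sequential resampling.

Intensities are processed as doubles regardless of the on-disk type; masks
and labels as integers. NIfTI-1 I/O (plain or gzipped) stores volumes as
float64, so write-read round trips are bit-exact; the affine is stored in
the sform (code 2) only, because quaternion (qform) encoding cannot
represent anisotropic voxel scaling exactly.

## The head phantom

`make_head_phantom()` builds a rodent-like head on a 64 x 64 x 32 grid of
0.2 x 0.2 x 0.5 mm voxels (the in-plane/through-plane anisotropy of typical
rodent 2D multislice acquisitions): a bright scalp/skull shell
(intensity 1.3), a dark gap (0.02), a brain ellipsoid with semi-axes
4.2 x 4.8 x 3.2 mm carrying a bright cortex-like shell (1.0, outer 15% of
the elliptical radius), a mid-intensity interior (0.6) and two dark
ventricle-like inclusions (0.15, 5% of brain volume by default), on a
zero background. Intensities are relative to cortex = 1.

Two deliberate design features:

* **Intra-tissue texture.** Brain tissue is modulated by a fixed smooth
  pattern (two cosine products, amplitudes 0.08 and 0.06, wavelengths
  1.9–3.4 mm). A purely concentric piecewise-constant phantom leaves
  orientation almost unidentifiable to any intensity metric — the
  similarity surface develops a spurious basin at identity. Real tissue
  has internal structure; the texture restores that identifiability. It is
  even in every axis, so the phantom stays exactly mirror-symmetric about
  the mid-sagittal plane and symmetric under 180-degree in-plane rotation.
* **Gap width.** The brain–skull gap defaults to 1.0 mm, twice the
  through-plane voxel. The histogram-based extraction depends on the brain
  forming its own connected component; the gap must therefore survive not
  only voxelisation but also the ~1-voxel interpolation blur introduced
  when imperfectly aligned subjects are averaged into a template.

Corruptions with ground truth: multiplicative bias fields (seeded random
quadratic polynomial, mean exactly 1, range within 1 ± amplitude), known
rigid/affine/nonlinear deformations, per-frame rigid motion for BOLD
series, and FAIR inversion-recovery signal series (below). Noise is
additive Gaussian (amplitude relative to cortex intensity), a documented
simplification of Rician magnitude noise; at the SNRs used (>= 20) the
difference is negligible away from the background. Every generator is a
pure function of its spec and seed.

What the phantom does *not* emulate: k-space acquisition, EPI ghosting and
susceptibility dropout, partial-volume fractions at tissue borders (voxels
are classified by their centres), coil-profile bias shapes beyond low-order
polynomials, and anatomical variability between subjects (the template
cohort is one anatomy under known rigid motions). Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions, not
performance on any particular scanner's data.

## Bias-field correction

The field is modelled as `exp(P(x))` with `P` a polynomial of order 2–4
(default 3) in centred, normalised world coordinates, fitted by least
squares to log-intensities inside a head mask (auto-derived by
histogram-valley thresholding when not supplied). Anatomy itself has
smooth structure — for an ellipsoidal brain the squared elliptical radius
is exactly quadratic — so a naive full-order fit absorbs tissue contrast
into the "field". The estimator therefore targets a single reference
tissue class:

1. fit a **linear** field only (too stiff to absorb anatomy, enough to
   remove the first-order trend);
2. locate the sharpest mode of the residual histogram (64 bins, Gaussian
   smoothing sigma = 2 bins) — in textured brain tissue the untextured
   class is the sharpest — and keep voxels within 0.12 log-units of it;
3. refit the full-order polynomial on that class; iterate selection and
   fit (4 rounds).

The field is normalised to mean 1 over the head mask, and
`corrected * field` reconstructs the input to floating-point rounding by
construction. On the phantom with a known order-2 field of amplitude 0.3
the RMS log-field error is reduced by ~99%. Re-running on corrected output
yields a field within 0.05 of 1 (near-idempotence). The approach is the
same single-class-targeting idea as white-matter-referenced normalisation
in the established tools, with a polynomial instead of a spline hierarchy.

## Brain extraction and the mask report

`extract_brain()` thresholds at the deepest smoothed-histogram valley
between the two most prominent modes (or at a user fraction of the robust
maximum, the 99th percentile), applies a one-voxel morphological opening
and closing, keeps the largest 6-connected component and fills internal
holes (recovering dark ventricles). On strongly anisotropic grids (voxel
aspect > 2) the opening is restricted to the fine in-plane axes — a
one-voxel through-plane erosion at 2.5x anisotropy would amputate the thin
polar caps of the brain.

`brain_segmentation_report()` screens a set of candidate thresholds with
five measures per mask: volume (mm^3), right-left / anteroposterior /
inferior-superior extents (world-space bounding boxes along the RAS axes,
including the bounding voxels' width), and the mid-sagittal symmetry
correlation. Thresholds whose extraction fails produce a row of `NA`s
rather than an error, so a whole sweep can be inspected numerically.

The mid-sagittal plane is parameterised as an offset along x plus two
small tilts (the brain is imaged roughly axis-aligned; a full 3-DOF plane
search adds cost without benefit). The search is a coarse grid (offsets
over the central third, tilts ±10° in 2° steps, evaluated on a x2
downsampled mask) followed by Nelder-Mead refinement. The symmetry score
is the Pearson correlation between the mask and its reflection, computed
over the **union of the two supports** (whole-grid correlation is inflated
by agreeing background) with the reflection sampled by **trilinear**
(partial-volume) weights: a binary nearest-neighbour reflection scores 1
only exactly on-lattice and near 0 half a voxel away, which makes the
objective a lattice comb that no local search can climb; the soft
reflection makes it smooth while still scoring exactly 1 for an exactly
symmetric mask.

## Registration

### Metric

The similarity is normalised mutual information,
`NMI = (H(A) + H(B)) / H(A, B)`, from a 32-bin joint histogram (8 bins
minimum; bin count is reduced proportionally at coarse pyramid levels).
The public `nmi()` evaluates it over the overlap of nonzero supports with
1st–99th percentile intensity limits. Inside the optimiser three details
differ, all to keep the objective smooth in the parameters: the histogram
domain is the *fixed* target support (a domain that moves with the
transform makes the metric discontinuous), intensity limits are frozen per
level, and both images are lightly smoothed (one 1-2-1 pass per axis).
The smoothing matters more than it looks: a moving image that has been
resampled carries interpolation blur, and matching it against a sharp
fixed image biases the optimum toward whole-voxel alignments ("grid
locking") and slight scale shrinkage; smoothing both sides symmetrises
the comparison. An SSD option exists for same-contrast pairs.

When brain masks are given they gate the metric (brain-extracted images)
on **both** sides — the estimated transform still maps whole heads.
Masking only one side is a degenerate objective: a brain-only source
compared against a whole-head target is genuinely best matched by
collapsing the brain into the bright head centre.

### Rigid and affine

Six parameters (rotations in degrees about the target grid centre,
translations in mm) or twelve (plus log-scales and shears), optimised
over a multiresolution pyramid (x4, x2, x1 block-mean downsampling;
factors are reduced automatically so no level drops below ~8 voxels per
axis). The per-level optimiser is Powell's direction-set method with Brent
line searches — derivative-free, deterministic, and able to follow the
rotation–shear ridges of the affine similarity surface on which simplex
methods collapse. The coarsest rigid level is preceded by an exhaustive
rotation sweep (±9° in 3° steps per axis) that guards against the
secondary basin at identity that near-elliptical anatomy produces. The
affine search starts from the rigid solution. Initialisation is support-
centroid alignment; everything is deterministic, so identical inputs give
bit-identical transforms.

On the full-size phantom, known rigid perturbations (≤10°, ≤5 voxels) are
recovered to well under 0.5° / 0.25 voxel, and affine scales in 0.9–1.1 to
better than 0.01.

### Nonlinear (free-form deformation)

The displacement field is a tensor-product cubic-B-spline lattice of
control-point displacements — a C^1 piecewise-polynomial mapping. Levels
run coarse to fine: control spacing starts at a quarter of the field of
view and halves per level (`max_level` levels, default 2). Control
displacements are hard-capped at 0.4 x spacing, a classical sufficient
condition for the spline mapping to remain diffeomorphic; levels are
*composed* (not summed), so the final mapping is a composition of
diffeomorphisms, and the discrete Jacobian determinant of the result is
verified positive at every interior voxel (violation aborts).

Within a level the data term is the SSD of 99th-percentile-normalised
images, minimised by a diagonally preconditioned Gauss-Newton iteration
(default 60 per level) with backtracking line search. The gradients are
the *exact* partial derivatives of the trilinear interpolant — a smoothed
central-difference image gradient is not a descent direction for the
sampled objective near its optimum and stalls about 25% short. Displacement
fields are sampled with edge-clamped interpolation wherever they are
composed or inverted; a hard zero outside the field's grid would fabricate
a discontinuity at the border.

Fields are inverted by the fixed-point iteration
`e_{k+1}(x) = -d(x + e_k(x))` (at most 50 iterations, mean-update
tolerance 1e-4 mm), which converges for capped fields; the round-trip
residual is ~0.1 voxel or better.

### Per-slice EPI correction

EPI distortion is in-plane and varies by slice, so the EPI reference and
the anatomical image (already on the EPI grid) are split along z and each
EPI slice is registered to its anatomical slice with the 2D version of the
FFD machinery. Slices with ≤1% nonzero voxels in either image keep an
identity warp. A per-slice model is deliberately more conservative than a
global 3D warp: it cannot invent through-plane deformation. The injected
quadratic distortion (≤2 voxels) is recovered to ~0.13 voxel mean in
the brain.

## Group template construction

The multi-level iterative scheme: median-normalise each bias-corrected
head image (median intensity 1 within its brain mask), average the images
centred on their brain-mask centroids (the rough initial template), then
repeatedly register every subject to the current template and re-average,
increasing the transform family by stages — default schedule centroid →
rigid x2 → affine x2 → nonlinear (levels 1, then 2). A stage ends early
when the mean voxelwise relative template change drops below the schedule
tolerance (1e-4).

Three safeguards keep the iteration accurate and monotone. First, the
very first rigid pass targets a sharp reference — the centred first
subject — because the centroid average is blurred wherever subjects
disagree, and registering against it can settle into a blurry fixed
point (subjects misaligned because the target is blurred, and vice
versa); from the next pass on, the evolving average is sharp enough to
take over as the symmetric target. Second, the metric domain of the
linear stages is restricted to a consensus brain mask (majority vote of
the resampled subject masks) on the target side only: this keeps the
smeared skull ring of an early average out of the metric, while the
moving subject keeps its whole-head intensities — a hard mask edge on
the moving image costs an order of magnitude in rotational accuracy.
Third, a stage's new transform for a subject is accepted only if it
does not lower that subject's whole-image NMI against the target;
otherwise the previous transform is kept. The convergence log records, per iteration, the mean
relative template change and the mean pairwise NMI of the resampled
subjects; on the rigidly perturbed phantom cohort the final template's
auto-extracted mask overlaps the true anatomy with Dice ≈ 0.99.

Averaging is the arithmetic mean (a trimmed option drops the voxelwise
min and max, for ≥4 subjects); the template grid defaults to the first
subject's grid. Subject order does not affect the result beyond float
summation order.

## BOLD and ASL pipelines

**Slice timing** linearly interpolates each voxel's time course to the
acquisition time of the reference slice (the slice acquired in the middle
of the volume), clamping the first and last frames. Linear interpolation
is exact for signals linear in time; no sinc kernel is used, a documented
simplification.

**Realignment** rigid-registers every frame to frame 1 over a two-level
pyramid and resamples; frame-1 parameters are exactly zero by
construction. The default metric is NMI on the (internally) smoothed
frames: with SSD the interpolation blur of a moved frame grid-locks the
optimum about half a voxel away, outside the accuracy this package aims
for; SSD remains available as the fast option. Simulated motions of
≤1.5 voxels are recovered to ~0.05 voxel RMS.

**Coregistration** reduces the modality to a representative volume — the
temporal mean after realignment for BOLD (median optional), the fitted
equilibrium-magnetisation M0 map for FAIR ASL — reorients the anatomical
image to the modality axes, optionally estimates the modality-to-
structural rigid transform and applies its inverse to the structural
image (or assumes negligible inter-scan motion in `reorient_only` mode),
and finishes with the per-slice distortion correction.

**Template-space processing** composes the per-slice warps, the rigid
transform and the structural-to-template chain and applies them in one
interpolation; `inverse_transform_towards_modality()` inverts every
element and applies them in reverse order, carrying template-space images
(e.g. atlases, with nearest-neighbour interpolation) into the distorted
native frames. Stage results can be memoised in a work directory keyed by
content hashes of inputs and parameters; a cache hit is bit-identical to
recomputation.

## FAIR perfusion quantification

The magnitude inversion-recovery model per voxel and inversion time TI:

    S(TI) = | M0 (1 - 2 alpha exp(-TI / T1)) |

with equilibrium magnetisation `M0 >= 0`, apparent relaxation time
`T1 > 0` (s) and inversion efficiency `alpha` in [0.5, 1]. Fitting the
magnitude directly handles the polarity flip at the null point without a
polarity-restoration step. Initialisation is a grid search over T1
(0.2–3.0 s, 13 points) crossed with three alpha candidates, using the
closed-form least-squares M0 for each; refinement is a damped Gauss-Newton
iteration vectorised across voxels with box constraints. The fit runs in
two passes: the inversion efficiency is a property of the pulse, not of
the voxel, so after a per-voxel first pass alpha is fixed at its median
and T1/M0 are refitted. This matters for accuracy — a per-voxel alpha
bounded above by 1 can only err downward under noise, and its strong
negative coupling with T1 (correlation about -0.76 at SNR 50) would
otherwise inflate T1 by ~1% and bias region-median CBF by ~8%. For a
FAIR pair the two series share one inversion pulse, so the recommended
practice (followed by the validation suite) is to estimate the common
efficiency from both series and pass it to both fits via the `alpha`
argument; this halves the residual draw-to-draw CBF bias again. Voxels whose
relative RMS residual exceeds 20% (a QC default, configurable) or that
carry no signal are excluded from the fit mask; excluded voxels hold `NA`
in every output map. Noiseless simulations are recovered to machine
precision; at 2% noise the median T1 error is below 1%.

CBF uses the FAIR difference of apparent relaxation rates:

    CBF = 6000 * lambda * (1 / T1_sel - 1 / T1_ns)   [ml/100g/min]

with `lambda` the blood–brain partition coefficient (default 0.9 ml/g, the
literature standard; both `lambda` and the 6000 unit constant are
arguments). The selective (slice-selective inversion) series decays faster
wherever perfusing blood carries fresh magnetisation, so `T1_sel < T1_ns`
and CBF is positive in perfused tissue. CBF is computed on the
intersection of the two fit masks; negative (noise-driven) values are kept
but counted in a QC field. The map is exactly antisymmetric under swapping
the two fits and exactly linear in lambda. `regional_summary()` reports
per-label count, median, quartiles, Tukey adjacent values, mean and SD.

## Evaluation

Dice is the exact set-count formula `2|A∩B| / (|A| + |B|)`; both masks
empty is defined as 1 (trivial agreement) and exactly one empty as 0,
because the raw formula is 0/0 there. `regional_dice()` applies it per
label id (background 0 excluded), one row per label present in either
image; labels are compared by integer id only.

## Problem sizes and determinism

The validation suite runs the full 64 x 64 x 32 phantom for every
acceptance-style check (registration recoveries, template construction,
distortion correction, realignment) and a half-resolution 32 x 32 x 16
phantom for unit tests, whose tolerances are proportionally wider where
they are resolution-bound. FAIR fitting is validated on a two-region
24 x 24 x 10 phantom at SNR 50. Every stochastic input is seeded and every
algorithm is deterministic (no stochastic restarts, no parallel reduction
order), so reruns are bit-identical.

## Known limitations

* Reorientation handles axis permutations and flips; genuinely oblique
  acquisitions are approximated by their nearest axis frame (warned).
* The bias model is a global polynomial; fields with sharper structure
  than order 4 will be under-fitted.
* The histogram extraction presumes separable background/tissue modes and
  a dark gap isolating the brain from the scalp/skull; it is not a
  general-purpose skull stripper.
* Linear registration against a *blurred* moving image retains a small
  scale bias (~0.03–0.04) when the metric is brain-masked; the unmasked
  configuration does not show it.
* The FAIR model fits a single compartment with per-voxel M0 and a
  global (per-series) inversion efficiency; transit-time and
  multi-compartment effects are out of scope.
* 2D slice-timing, motion and distortion corrections are estimated
  independently; no joint slice-to-volume model is attempted.
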