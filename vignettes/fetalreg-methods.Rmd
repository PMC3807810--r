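---
title: "Aligning fetal brain MRI with 3D ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning fetal brain MRI with 3D ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fetal brain MRI and 3D ultrasound (US) depict largely complementary
features. MR contrast comes from tissue relaxation times and separates
white matter, cortex and CSF; B-mode US intensity comes from acoustic
impedance differences and tissue microstructure, and is dominated by a
small set of strongly echogenic structures — the skull, the falx
(interhemispheric membrane), the brain surface, the choroid plexus, the
septi pellucidi, the cerebellum and deep grey matter. A direct
multi-modal similarity between the two images is therefore weak. The
approach implemented here sidesteps it: segment those US-visible
structures in the MR volume, render them as an artefact-free
*pseudo-ultrasound* image in which each structure has a uniform intensity
ordered by echogenicity, and register that pseudo image to the real US
volume with a robust block-matching algorithm. The registration problem
becomes effectively mono-modal and can use plain normalised
cross-correlation (NCC) locally.

## Pipeline overview

`run_pipeline()` chains the stages; each is usable on its own:

1. **(optional) Super-resolution reconstruction** (`reconstruct_volume`)
   of an isotropic MR volume from thick-slice stacks.
2. **EM tissue classification** (`segment_em`) of the MR volume into WM,
   cortex, deep GM, brainstem, cerebellum, CSF and background, with
   atlas priors and interleaved multiplicative bias-field correction.
3. **Structure mapping** (`split_hemispheres`, `estimate_skull_shell`,
   `extract_brain_surface`, `build_structure_map`): hemisphere
   separation with a synthetic midline/falx, a skull shell grown from
   the brain mask, a thin echogenic surface layer, plus manually
   supplied choroid plexus / septum / cerebellar-WM labels.
4. **Pseudo-US synthesis** (`assign_pseudo_intensities`) and US
   preprocessing (`preprocess_us`).
5. **Robust block-matching registration** (`register_us`): local NCC
   matching of small blocks plus least-trimmed-squares (LTS) rigid and
   affine estimation over a two-level resolution pyramid.
6. **Evaluation** (`dice_overlap`, `barycentre_distance`, `mean_tre`,
   `max_euler_rotation`).

All grids are axis-aligned with world coordinates in millimetres; voxel
`(i, j, k)` (0-based) sits at `origin + (i, j, k) * spacing`. Transforms
are 4×4 homogeneous world-coordinate maps; resampling uses the pull-back
convention (the transform maps output-space points into input-space
points) with fill value 0, matching the dark background of both
modalities. Euler angles are reported in the intrinsic z–y–x convention;
the rotation factor is extracted by polar decomposition so scale and
shear never leak into reported angles. The convention affects reported
angle values by bounded amounts; it is fixed and documented here because
no single convention is canonical.

## Super-resolution reconstruction

The acquisition model is linear: each acquired voxel `j` of a
thick-slice stack sees the reconstruction `x` through Gaussian PSF
coefficients `m_ij` (through-plane FWHM equal to the slice thickness,
in-plane FWHM 1.2× the in-plane resolution, truncated at 3σ and
normalised to sum 1). The reconstruction minimises the robustly weighted
data term `sum_j w_j (y*_j − y^s_j)^2` plus an isotropic Charbonnier
edge-preserving penalty `λ Σ sqrt(ε² + |∇x|²)` with defaults
`λ = 0.02 ×` and `ε = 0.01 ×` the intensity range — a standard
edge-preserving choice; the weights `w_j` are products of voxel-level
and slice-level inlier posteriors from a two-component EM
(zero-mean Gaussian inliers, uniform outliers; the slice level runs on
the per-slice robust residual scale, 1.4826 × median absolute
residual). The densities for this EM are a documented choice — the
classification idea fixes neither.

Numerical details that matter:

* The model is linear, so line searches reuse the simulated gradient
  (`A(x − t g) = Ax − t·Ag`); one forward simulation per descent step.
* Per-stack intensity scales are re-fit by weighted least squares each
  outer iteration *after* the robust weights, and the scale/volume gauge
  freedom (`(x, s) → (x/c, s/c)` leaves the data term invariant) is
  anchored by normalising the mean scale to 1.
* After the first robust weighting pass the volume is re-initialised by
  weighted back-projection, because the unweighted start is already
  contaminated by any corrupted slices.
* The objective is non-increasing within each outer iteration (fixed
  weights); across outer iterations the weights and scales change, so
  only the per-iteration traces are monotone (`objective_trace`).

Slice poses are inputs; motion estimation is out of scope.

## EM segmentation and bias correction

Posteriors are the Bayes combination of Gaussian class likelihoods with
atlas priors; the background class uses a two-Gaussian mixture because
amniotic fluid and true background have very different intensities.
Class means and variances are posterior-weighted moments. The
multiplicative bias field is estimated directly (no log transform of the
image): the bias-free image estimate is the inverse-variance-weighted
posterior blend `e_i = Σ_k p_ik μ_k/σ_k² / Σ_k p_ik/σ_k²`, the log
residual `r_i = log(x_i*/e_i)` is smoothed with a weighted Gaussian
(weights `x_i* Σ_k p_ik/σ_k²`, σ = 20 mm by default), re-centred to zero
mean over the brain mask, and removed multiplicatively. Whether the
posterior weights carry `σ_k²` or `1/σ_k²` is ambiguous in parts of the
literature; this implementation uses inverse-variance weighting
throughout, the form consistent with the weighted-least-squares reading.
The zero-mean re-centring fixes the global gauge of the multiplicative
field — scale moved into the bias is indistinguishable from scale in the
class means, so some convention is required, and the synthetic MR
generator uses the same one.

Initialisation uses prior-weighted intensity statistics; the background
mixture starts at the 10th and 60th intensity percentiles of low-prior
voxels (the amniotic-fluid component is not specified anywhere, so this
is a pragmatic, documented default). Convergence: largest class-mean
change below 0.1% of the intensity range, or 50 iterations.

## Structure mapping

* **Hemisphere split.** WM cores are WM voxels at least 1.5 mm from the
  WM surface (exact Euclidean distance transform), keeping the two
  largest 26-connected components; ties are broken by centroid
  x-coordinate (left = smaller x) for determinism. Distance maps from
  each core are regularised with a 10 mm Gaussian; each brain voxel goes
  to the nearer core; voxels whose regularised distances differ by at
  most one voxel size become the midline, emulating the thin
  falx/CSF gap visible on US.
* **Skull.** The fetal skull closely follows the brain mask (tissues +
  CSF); the shell is all outside voxels within 2 mm of the mask.
* **Brain surface.** Mask voxels within 0.66 mm (two voxels at the
  0.33 mm template resolution) of the complement; the thickness of this
  echogenic layer is not specified anywhere, so it is configurable.
* **Assembly.** WM and cortex merge into per-side cortical hemispheres
  (their boundary is invisible on US). On overlap a fixed precedence
  applies — skull > choroid/septum/midline > surface > cerebellum(/WM) >
  DGM/brainstem > hemispheres > CSF — our rule; the structure inventory
  itself has no overlap semantics. The whole midline is labelled as the
  falx class (the membrane tier), including where the anatomical falx is
  absent, since its US appearance is what is being emulated. In
  `"young"` gestational-age mode cerebellar WM is a separate darker
  class; in `"old"` mode the folded cerebellum is uniformly bright and
  any cerebellar-WM labels are ignored.

## Pseudo-ultrasound synthesis

Each structure receives a uniform intensity; only the *ordering*
matters, because block-wise NCC is invariant to monotone remapping
within the block's tiers. Default tiers (brightest to darkest): skull
1.00; choroid plexus, septi pellucidi and midline/falx 0.80; brain
surface 0.65; cerebellum 0.50; DGM and brainstem 0.35; cerebral
hemispheres (with cerebellar WM, which is hypoechogenic in younger
fetuses) 0.20; CSF 0.05; background 0. No speckle is added — speckle
cannot be predicted from MR, so the real US is instead smoothed with a
small Gaussian (0.5 mm default). Cerebellar WM is placed with the
hemispheres tier rather than its own tier: it is described as
hypoechogenic relative to the bright cerebellar cortex, and the darkest
parenchymal tier is the closest match.

## Block-matching registration

At each pyramid level (2 mm then 1 mm isotropic) and model stage (rigid,
then affine), the algorithm alternates two steps until the largest
bounding-box-corner displacement between successive transforms is below
0.1 mm (or 10 iterations):

1. **Matching.** The pseudo image is warped through the current
   transform onto the target grid, so block *content* is
   rotation-compensated before comparison — without this warp every
   match carries a tangential bias under rotation and the iteration has
   no fixed point at the true transform. Blocks are 3×3×3 voxels on a
   2-voxel lattice (overlapping blocks stabilise the robust fit at
   modest cost). Source blocks need nonzero variance; target candidates
   need variance ≥ 0.04 × the target intensity range — a rule calibrated
   for byte-scaled B-mode volumes, which is why the simulator emits
   0–255 intensities. Each source block searches all integer offsets
   within ±7 voxels; the best NCC (or squared NCC for the correlation
   ratio option, equivalent under a per-block affine intensity model)
   wins, with ties resolved by the smaller offset then lexicographically.
2. **Estimation.** The displacement field feeds least trimmed squares:
   fit on the current inliers (affine by linear least squares; rigid by
   Procrustes via the SVD of the cross-covariance with determinant
   correction), rank squared residuals, keep the best 75%, refit until
   the inlier set repeats. The trimmed objective is non-increasing
   (classic concentration steps); `h = 1` is ordinary least squares.
   Trimming is what discards source blocks whose true counterpart is
   missing from the US (shadowed or outside the field of view).

Initialisation is a user-supplied transform (identity by default); the
capture range of the warped matching extends to rotations of roughly
30°, beyond which an explicit re-orientation is required, as it is in
clinical practice. Sub-voxel search is not attempted: integer offsets at
the 1 mm final level leave a noise floor of a fraction of a voxel in the
recovered transform (about 1 mm at the bounding-box corners), which is
the accuracy floor quoted by the tests.

## The synthetic phantom: what it emulates and what it does not

`make_label_phantom()` builds a deterministic fetal-head phantom: a
triaxial head ellipsoid (semi-axes 36, 28, 24 mm — occipitofrontal >
biparietal > height, roughly a 22-week head), a 2 mm skull shell, a CSF
layer, a thin echogenic surface, hemispheres split by a one-voxel
midline, lateral-ventricle CSF lakes containing elongated choroid
bodies, bilateral deep grey matter, brainstem, cerebellum with a darker
WM core, and a septum slab, on a 96³ grid at 1 mm spacing.

Two departures from plain nested ellipsoids are deliberate and
load-bearing:

* a seeded random radial perturbation of the shells (2 mm RMS, 5 mm
  correlation length, mirrored to keep bilateral symmetry), and
* CSF-filled wedges emulating the Sylvian fossae and major sulci,
  draped by the bright surface tier.

Exact smooth concentric ellipsoids are *rotationally self-similar*:
sliding along such a shell produces a block that matches perfectly, so
no feature-based method — and no sonographer — could anchor a rotation
to them. Real anatomy carries gyral and skull-table irregularity at
exactly the block scale; the perturbation and fossae restore that
property, making the phantom a fair emulation rather than an impossible
abstraction.

`simulate_mr()` adds per-class Gaussian noise and a smooth polynomial
multiplicative bias (zero-mean log-bias over the head, the same gauge
the estimator fixes). `simulate_us()` resamples the pseudo image through
a ground-truth transform and degrades it with depth attenuation from a
virtual probe, multiplicative log-normal speckle (speckle is modelled by
its disruptive statistics, not coherent interference — it carries no
registration signal either way), a probe shadow cone, additive noise,
and a 0–255 output scale. Reverberation artefacts are not modelled.
What passing phantom tests do *not* show: performance on real acoustic
physics (refraction, reverberation, anisotropic PSF), true fetal
anatomy, or inter-subject anatomical variability.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: the 96³ phantom with
ten random rigid perturbations (rotations up to 30°, speckle sd 0.2,
attenuation 0.008/mm, a shadow cone occluding 20% of the brain) for
transform recovery; a 64³ three-class phantom at SNR 10 and bias
amplitude 0.2 for EM recovery; 48³ volumes with three orthogonal stacks
(20% corrupted slices in the robust case) for the reconstruction; and
constructed hand cases for the metrics. These sizes are the package's
chosen desk-scale study conditions; each registration takes tens of
seconds and the full acceptance run minutes on one CPU.

## Known limitations

* Oblique NIfTI direction matrices are rejected rather than resampled.
* Slice-to-volume motion correction is out of scope (poses are inputs),
  as are template propagation by non-rigid registration and the
  locally-affine non-linear extension of the block matcher.
* The registration noise floor is set by integer-voxel search at the
  finest level; applications needing sub-0.5 mm accuracy would need
  sub-voxel refinement.
* The EM background mixture assumes a bimodal background (dark + fluid);
  exotic backgrounds may need a different initialisation.
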