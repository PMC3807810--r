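# fetalreg

Rigid/affine registration of fetal brain MRI to 3D ultrasound via
pseudo-ultrasound synthesis and robust block matching.

## The problem

Fetal brain MRI and 3D B-mode ultrasound see largely complementary
features: MR separates tissues by relaxation properties; ultrasound is
dominated by a handful of strongly echogenic structures — the skull, the
falx, the brain surface, the choroid plexus, the septi pellucidi, the
cerebellum and deep grey matter — whose *ordering* of brightness is
reliable even when absolute contrast is not. Direct multi-modal
similarity measures are weak on this pair. `fetalreg` instead

1. segments the US-visible structures in a reconstructed T2w MR volume
   (EM classification with atlas priors and multiplicative bias-field
   correction, hemisphere splitting with a synthetic falx/midline, a
   skull shell grown from the brain mask, a thin echogenic surface
   layer),
2. renders them as an artefact-free **pseudo-ultrasound** image with one
   uniform intensity per echogenicity tier, and
3. registers that pseudo image to the real ultrasound volume by **robust
   block matching**: for every 3×3×3 block with features, the most
   similar target block within ±7 voxels is found by normalised
   cross-correlation (NCC), and the rigid or affine transform `T` is
   estimated from the resulting displacement field by least trimmed
   squares,

   `T* = argmin_T  Σ_{i=1}^{h} ‖ C_i + d_i − T(C_i) ‖²`,

   keeping only the `h = 75%` smallest squared residuals so that blocks
   whose counterpart is shadowed or missing in the ultrasound cannot
   corrupt the fit. The two steps alternate over a 2 mm → 1 mm
   resolution pyramid, rigid stage then affine stage.

The package also provides super-resolution reconstruction of the MR
volume from thick-slice stacks with EM inlier/outlier weighting, a fully
synthetic fetal-head phantom (MR appearance, ultrasound speckle /
attenuation / probe-shadow artefacts, known ground-truth transforms) so
every stage is testable without clinical data, and alignment metrics
(Dice, barycentre distance, mean target registration error, maximum
Euler rotation).

## Worked example

Simulate a degraded ultrasound volume from the phantom under a known
rigid transform, then recover the transform:

```r
library(fetalreg)

ph     <- make_label_phantom(phantom_spec(seed = 7))
pseudo <- assign_pseudo_intensities(ph$smap)

t_true <- affine_from_params(angles_deg = c(12, -8, 10),
                             translation = c(3, -2, 4),
                             center = ph$centre)
art <- us_artifact_spec(transform = t_true, speckle_sigma = 0.2,
                        attenuation_per_mm = 0.008,
                        shadow_halfangle_deg = 7, seed = 7)
us  <- preprocess_us(simulate_us(pseudo, art)$us)$us

reg <- register_us(pseudo, us)
reg
#> Pseudo-US to US block-matching registration
#>   translation (mm): 20.59, 0.47, -9.60
#>   Euler z-y-x (deg): 12.06, -8.35, 9.95
#>   max Euler rotation: 12.06 deg
#>   stages: 4, converged: TRUE, failed: FALSE
```

The recovered Euler angles (12.06, −8.35, 9.95)° match the simulated
(12, −8, 10)°; the mean voxel displacement error between the recovered
and true transforms over the brain is 0.24 mm, a quarter of the 1 mm
final-level voxel size. `summary(reg)` lists per-stage diagnostics
(iterations, field sizes, trimmed RMS residuals); `coef(reg)` returns
the 4×4 source→target world-coordinate matrix.

The full pipeline — EM segmentation of a simulated MR volume through to
the registered transform — is driven by `run_pipeline(pipeline_config(...))`,
and a thin command-line wrapper lives in `inst/cli/fetalreg.R`
(`simulate`, `register`, `run` subcommands). The methods vignette
(`vignettes/fetalreg-methods.Rmd`) documents the models, defaults and
design decisions.

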