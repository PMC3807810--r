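Package: fetalreg
Title: Fetal Brain MRI to 3D Ultrasound Registration via Pseudo-Ultrasound
    Block Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments a reconstructed T2-weighted fetal-brain MR volume into
    structures visible in B-mode ultrasound, synthesises an artefact-free
    pseudo-ultrasound volume from the segmentation, and registers it to a 3D
    fetal ultrasound volume with a robust block-matching algorithm that
    combines per-block normalised cross-correlation matching with
    least-trimmed-squares rigid/affine estimation. Also provides
    expectation-maximisation atlas-based tissue classification with
    multiplicative bias-field correction, super-resolution reconstruction of
    a volume from thick-slice stacks with robust outlier weighting, a
    synthetic fetal-head phantom generator (MR appearance, ultrasound
    speckle/attenuation/shadow artefacts) for end-to-end validation, and
    quantitative alignment metrics (Dice, barycentre distance, mean target
    registration error, maximum Euler rotation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
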