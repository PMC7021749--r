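Package: renalqmap
Title: Quantitative Multi-Parametric Renal MRI Mapping and Reproducibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative multi-parametric renal MRI analysis:
    voxel-wise T1 mapping from modified Look-Locker inversion recovery (MOLLI)
    series, apparent diffusion coefficient (ADC) mapping from multi-b-value
    diffusion-weighted imaging, and perfusion mapping from pseudo-continuous
    arterial spin labelling (pCASL) label/control/M0 sets via a single-
    compartment kinetic model. Includes contour-based kidney volumetry with
    every-slice and alternate-slice (linear area interpolation) protocols, a
    six-region renal ROI taxonomy (whole kidney, cortex, representative
    cortex, polar cortex, medulla) with summary statistics and
    corticomedullary ratios, and interobserver reproducibility statistics
    (two-way random average-measures ICC, coefficient of variation,
    Bland-Altman limits of agreement). A synthetic coronal kidney phantom
    generator with distinct cortex/medulla/pelvis compartments and a
    simulated second-observer contour model makes every pipeline stage
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    EBImage,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
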