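Package: bbbflow
Title: Blood-Brain Barrier Leakage and Cerebral Pulsatility from DCE-MRI
    and 4D Flow MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantitative pipeline for blood-brain barrier (BBB)
    integrity and cerebral arterial hemodynamics. Estimates the
    permeability-surface area product (PS) and fractional plasma volume (vp)
    with the Patlak model from dynamic contrast-enhanced (DCE) MRI, using
    variable-flip-angle T1 mapping with B1 correction and a vascular input
    function extracted from the superior sagittal sinus by seeded
    cross-correlation and centerline reduction. Derives per-vessel and distal
    arterial flow waveforms, pulsatility indices and total cerebral blood flow
    from 4D flow velocity and complex-difference volumes via 3D
    skeletonization and cross-sectional flow integration. Includes a digital
    phantom generator with exact ground truth (spoiled-gradient-echo signal
    model, Rician noise, pulsatile tube flow, synthetic cohorts) so that
    every stage is testable without patient data, plus the cohort-level
    association statistics (Pearson correlation, regression with confidence
    intervals, residualization, shared-variance PCA, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
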