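Package: dscleak
Title: Leakage-Corrected Relative Cerebral Blood Volume from DSC-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates relative cerebral blood volume (rCBV) from dynamic
    susceptibility contrast (DSC) MRI time series, without correction and
    with two model-based corrections for gadolinium extravasation through a
    disrupted blood-brain barrier: the unidirectional
    (Boxerman-Schmainda-Weisskoff) model, which estimates a susceptibility
    scaling factor K1 and a leakage rate K2 per voxel, and a bidirectional
    extension that additionally estimates the back-transfer coefficient Kep
    from the extravascular space to the vasculature. Includes the standard
    voxel quality control (5-SD signal-drop exclusion, tail-versus-baseline
    selection of nonenhancing voxels for the whole-brain reference curve),
    first-pass bolus-window location, trapezoidal rCBV integration with
    normal-appearing white matter normalization, voxelwise adjusted R-squared
    fit diagnostics, nonparametric cohort statistics (Wilcoxon signed-rank
    with Holm correction, Spearman correlation with tumor grade), and a
    seedable gamma-variate phantom generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    yaml,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
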