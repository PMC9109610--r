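Package: ventimap
Title: Ventilation Imaging from 4D Phase-Resolved Thoracic CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives regional lung ventilation maps from 4D phase-resolved
    cone-beam CT. Implements the two classical registration-based estimators
    (density change from Hounsfield units and the Jacobian determinant of the
    displacement field), a multiresolution demons deformable registration, a
    slice-based U-net regressor that maps phase stacks directly to a
    ventilation image, the shared post-processing chain (lung masking,
    percentile normalisation, box median filtering), and the evaluation
    statistics used to compare ventilation maps against a reference (masked
    voxel-wise Spearman correlation, functional-lung tertile Dice overlap,
    one-way ANOVA with Tukey HSD). A synthetic breathing-lung phantom with an
    analytic displacement field and closed-form ground-truth ventilation
    provides a fully verifiable test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
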