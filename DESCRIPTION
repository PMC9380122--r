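Package: ablmargin
Title: Biomechanical Deformable Registration and 3D Minimum-Margin
    Assessment of Liver Tumor Ablations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing percutaneous thermal-ablation outcomes of
    liver tumors from volumetric imaging. Implements biomechanical
    (linear-elastic finite-element) deformable registration of pre- and
    post-ablation liver images driven by surface-mesh correspondence,
    computation of the 3D minimum delivered ablation margin
    (distance-to-agreement) with a subcapsular correction, multiscale
    Hessian vesselness segmentation with sphere-of-interest focused rigid
    registration of follow-up scans, and a spherical-coordinate
    cone-tracing procedure that tests whether local tumor progression
    colocates with the region where the intended 5-mm margin was not
    achieved. A synthetic liver phantom generator with known ground-truth
    deformations supports end-to-end validation, and group statistics
    (Mann-Whitney U, ROC/AUC) reproduce a packaged per-patient margin
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    oro.nifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
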