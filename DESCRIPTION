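Package: radglioma
Title: Lesion-Location-Aware MRI Radiomics for Molecular Subtyping of
    Grade II/III Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics analysis for predicting the molecular
    subtype of lower-grade (WHO grade II/III) gliomas from conventional
    MRI, with lesion location encoded as atlas-occupancy features.
    Provides gray-level normalization to 256 levels, derived T2-edge and
    gadolinium z-score channels, mutual-information affine registration
    to an atlas grid, extraction of a 109-feature radiomic vector
    (first-order histogram, shape, and atlas-occupancy location
    features), voxel-wise Fisher exact lesion-frequency mapping with
    cluster-based permutation correction, and L1-penalized logistic
    subtype classification with institution-balanced train/validation
    splits. A seeded synthetic cohort generator emulates the statistical
    structure of a multi-institutional glioma cohort so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    nnet,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
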