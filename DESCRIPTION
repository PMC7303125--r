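Package: bmatquant
Title: Quantification of Bone Marrow Adipose Tissue from Co-Registered CT/PET Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies and quantifies bone marrow adipose tissue (BMAT) from
    co-registered CT and PET volumes. Provides Hounsfield-unit (HU) histogram
    analysis of marrow volumes of interest, ROC-based derivation of diagnostic
    HU cutpoints (Youden's J), threshold segmentation of marrow into adipose,
    red-marrow and bone compartments with adipose volumetrics (Ad.V/Ma.V),
    standardized uptake value (SUV) quantification per compartment,
    tissue-equivalent-material phantom density calibration for small-animal CT,
    gamma-count normalization to percent injected dose per gram with
    radioactive-decay correction, adipocyte histomorphometry metrics, and a
    parametric total-body model of tissue volumes and glucose-uptake capacity
    from anthropometrics. A synthetic phantom generator supplies paired CT/PET
    volumes, calibration phantoms, cohorts and adipocyte annotations with known
    ground truth so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
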