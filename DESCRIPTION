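Package: lvtransient
Title: Left Ventricular Volume Transient Analysis and Post-Infarction Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct left-ventricular (LV) cavity volume transients
    from short-axis segmentation stacks, extract conventional cardiac-phase
    metrics (systolic/diastolic timing, diastasis, passive and active filling,
    phase velocities), build an unsupervised PCA atlas of min-max normalized
    transients whose mode weights act as contraction biomarkers, and evaluate
    their prognostic value for major adverse cardiac events with backward
    stepwise linear discriminant and Cox models under repeated stratified
    k-fold cross-validation. A parametric synthetic-cohort generator provides
    ground-truth transients, mask phantoms, covariates and outcomes so that
    every stage of the pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    survival,
    signal,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
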