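Package: alpsflow
Title: Diffusion Tensor Image Analysis Along the Perivascular Space (DTI-ALPS)
    on Synthetic Phantoms and Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the DTI-ALPS glymphatic index and its
    downstream statistics. Provides a monoexponential diffusion-tensor signal
    model with log-linear least-squares tensor fitting, FSL-dialect bval/bvec
    and NIfTI input/output, region-of-interest extraction of directional
    diffusivities and the per-hemisphere DTI-ALPS ratio index, test-retest
    intraclass correlation, a cohort statistics battery (normality-gated
    ANCOVA or Quade rank analysis of covariance, chi-square tests, partial
    correlation with covariate adjustment, ROC/AUC, Benjamini-Hochberg
    correction), and Preacher-Hayes simple mediation with a percentile
    bootstrap for the indirect effect. Synthetic diffusion phantoms with a
    closed-form ALPS ground truth and synthetic patient/control cohorts with
    a known mediation structure make every stage testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
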