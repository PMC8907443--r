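Package: deltarad
Title: Delta-Radiomics Modeling of Tumor Regression on Longitudinal
    MR-Guided Radiotherapy Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delta-radiomics analysis of longitudinal low-field
    MR images acquired during MR-guided radiotherapy of locally advanced
    rectal cancer. Provides biologically-effective-dose (BED) alignment of
    imaging timepoints across fractionation schemes, an IBSI-style
    morphological / first-order / textural feature extractor for gross
    tumour volume (GTV) masks, delta-feature construction as ratios to the
    simulation scan, the early regression index, and the univariate
    Wilcoxon-Mann-Whitney screening, logistic modeling and bootstrap-ROC
    cascade used to predict 2-year disease-free survival. A synthetic
    cohort generator produces six-timepoint shrinking, textured tumour
    phantoms with a configurable outcome effect carried by the change in
    the GTV surface-to-volume ratio, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
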