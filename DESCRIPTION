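Package: cvpwave
Title: Central Venous Pressure Waveform Morphology and Tricuspid
    Regurgitation Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating central venous pressure (CVP) waveform
    morphology to the echocardiographic severity of tricuspid regurgitation
    (TR). Provides a synthetic cohort generator with known ground truth,
    ECG-anchored beat segmentation, artifact rejection by k-Shape clustering
    with the shape-based distance, detection of the C and V waves and X and
    Y descents, the pressure-difference indices V-Y, X-Y and C-Y with
    Jonckheere-Terpstra trend tests, Steel-Dwass multiple comparisons and
    ROC analysis with Youden cutoffs and Hanley confidence intervals, and a
    Transformer encoder beat classifier with attention-rollout explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
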