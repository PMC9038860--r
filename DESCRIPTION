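Package: vncamarrow
Title: Bone Marrow Quantification from Virtual Non-Calcium Dual-Energy CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated estimation of bone-marrow infiltration in plasma-cell
    disorders (multiple myeloma, smoldering myeloma, MGUS) from dual-energy
    CT. Implements a three-compartment (fat, soft tissue, bone mineral)
    attenuation model with a two-basis calcium-suppression transform that
    produces virtual non-calcium (VNCa) volumes, rule-based vertebra
    labeling with bottom-up selection of 17 vertebrae and 3-mm cortical
    erosion to build a marrow volume of interest, attenuation histograms and
    the non-fatty portion of bone marrow statistic, phantom-less in-body
    calibrated bone mineral density measurement, and the inference layer:
    bounded-response logit regression with White robust errors,
    heteroskedasticity and collinearity diagnostics, ROC analysis with
    Youden thresholds and power, ICC(2,1) reader agreement, and majority
    voting. A synthetic dual-energy spine phantom generator with known
    compartment composition makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    pROC,
    sandwich,
    lmtest,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr,
    tidyr
Config/testthat/edition: 3
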