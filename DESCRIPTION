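Package: sabrqa
Title: Quality-Assurance Analysis for Stereotactic Ablative Radiotherapy Dummy Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-phase quality-assurance analysis of a
    multicenter stereotactic ablative radiotherapy (SABR) dummy run:
    inter-institutional contour agreement (Dice similarity coefficient on
    summed target volumes, pairwise DSC, ICC(2,1), non-parametric bootstrap
    confidence intervals) and treatment-plan compliance review (PTV coverage,
    R50%, D2cm, high-dose spillage, organ-at-risk dose constraints with
    major/minor deviation grading and multi-target exemptions, PTV-EVAL).
    Includes a synthetic phantom cohort generator with controllable Dice
    agreement and analytically known dose metrics, so the whole pipeline is
    testable without clinical data.
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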