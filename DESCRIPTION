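Package: kanoqfd
Title: Kano-AHP-QFD Requirement Prioritization for Product Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A four-stage requirement-prioritization pipeline for user-centred
    product design, built around three classical decision-analysis methods:
    Kano satisfaction classification of paired functional/dysfunctional
    questionnaire answers with Better-Worse (satisfaction/dissatisfaction)
    coefficients and questionnaire-reliability QC (Cronbach's alpha, KMO,
    Bartlett's sphericity test); analytic hierarchy process (AHP) weighting of
    a goal/criteria/indicator hierarchy from Saaty pairwise-comparison
    matrices with lambda-max consistency checking; and quality function
    deployment (QFD) translation of comprehensive requirement weights into
    ranked technical-feature weights through a House of Quality relationship
    matrix. Includes seeded generators for synthetic questionnaires, pairwise
    matrices and relationship grids, plus a bundled mobility-scooter design
    case study whose published tables the package reproduces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
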