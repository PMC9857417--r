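Package: grequiv
Title: Polygenic Risk Scores, Case-Control Models, and Genetic Risk
    Equivalents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing polygenic risk scores (PRS) from allele
    dosages and a variant scoring table, transforming scores to
    control-referenced percentiles and tertiles, fitting case-control
    logistic regression models of lifestyle exposures and the PRS
    (including multiplicative interaction tests, PRS-stratified and joint
    classification analyses, subtype heterogeneity tests, and collinearity
    diagnostics), and expressing exposure associations as genetic risk
    equivalents (GRE): the difference in PRS percentiles whose log-odds
    association matches that of the exposure, with delta-method, Fieller,
    and parametric-bootstrap confidence intervals. A retrospective
    case-control simulator with known generative effect sizes provides a
    ground-truth surface for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
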