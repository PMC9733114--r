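Package: healthineq
Title: Health Inequality Summary Measures from Complex Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design-based estimation of subgroup prevalence for a binary
    health indicator under multistage stratified cluster sampling (Taylor
    linearization, logit-transformed confidence intervals), together with
    the four summary measures of health inequality used in equity
    monitoring: Difference (D), Ratio (R), Population Attributable Risk
    (PAR) and Population Attributable Fraction (PAF), each with delta-method
    or cluster-bootstrap uncertainty intervals. Includes a simulator for
    MICS-like household surveys (systematic PPS cluster selection, asset
    based wealth quintiles via principal component analysis, intra-cluster
    correlation on the log-odds scale) with closed-form truth, and a
    packaged reproduction of a published two-survey analysis of
    insecticide-treated net use by pregnant women in Ghana.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
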