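Package: ecdiglobal
Title: Survey-Based Estimation and Global Projection of Low Early
    Childhood Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the prevalence of low early childhood
    development from caregiver-reported Early Childhood Development Index
    (ECDI) responses in household-survey microdata, and for projecting
    those estimates to all low- and middle-income countries. Scores the
    ten ECDI items with reverse coding, classifies children as low in the
    cognitive and socioemotional domains, computes survey-weighted
    prevalences with Taylor-linearized cluster-robust standard errors,
    fits country-level ordinary-least-squares prediction models selected
    by exhaustive leave-k-out cross-validation, and converts predicted
    prevalences to child counts with confidence intervals built from
    cross-validation errors. A synthetic generator of MICS/DHS-like
    two-stage cluster survey microdata makes the whole chain testable
    against known ground truth without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
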