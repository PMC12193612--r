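Package: hequity
Title: Stage-Wise Income-Related Health Inequality and Horizontal Equity
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring income-related inequality in self-rated
    health among medical-insurance participants. Ordinal self-rated health
    is cardinalized to a continuous [0, 1] score via an ordered-probit
    latent index; concentration and Erreygers indices are computed over
    fractional income ranks at the four income states induced by an
    insurance scheme (initial income, after premium contribution, after
    out-of-pocket treatment spending, after reimbursement), with
    stage-to-stage changes, bootstrap standard errors, and subgroup
    analyses. A mean-normalized relative-deprivation index of health (whose
    population mean is the Gini coefficient of health) with
    quintile-membership regressions corroborates the index results, and
    indirect need-standardization of outpatient and inpatient utilization
    evaluates horizontal equity. A seeded synthetic cohort generator
    emulates survey microdata with a known income-health gradient for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
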