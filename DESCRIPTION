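Package: mpseimpact
Title: Health Impact Estimation for Mass Participation Sporting Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the public-health impact of mass participation sporting
    events (MPSEs) such as open-entry running events. From participant survey
    records, or from six aggregate framework parameters, the package computes
    the cumulative additional vigorous physical activity performed in
    preparation by initially inactive participants, converts the total minutes
    to quality-adjusted life years (QALYs) and values them against monetary
    cost-effectiveness thresholds. Includes a validated survey-record schema
    with CSV input/output, a seeded synthetic cohort generator for testing the
    full pipeline without raw survey data, descriptive and inferential cohort
    statistics (Welch t-tests, chi-square tests, 2x2 odds ratios, binary
    logistic regression), and a finite-population sample-size calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
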