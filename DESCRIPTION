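Package: delabelr
Title: Penicillin Allergy De-Labelling Algorithm and PEN-FAST Decision Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, traceable implementations of a five-question
    history-based algorithm for de-labelling suspected penicillin (beta-lactam)
    allergy and of the PEN-FAST point-score decision rule, together with
    diagnostic-accuracy statistics (sensitivity, specificity, predictive
    values with Wilson score confidence intervals, prevalence-adjusted
    predictive values) and a synthetic patient-cohort generator. The
    generator produces both a deterministic 800-record reference cohort whose
    complete outcome structure matches a published allergy-clinic case series,
    and seeded stochastic cohorts drawn from the same marginal distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
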