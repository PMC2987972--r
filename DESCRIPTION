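Package: comorbscreen
Title: Hypothesis-Free Comorbidity Screening in Claims-Shaped Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds matched case/control cohorts from administrative-claims
    style tables (persons, claims, enrollment spells), pairs cases to controls
    by greedy digit-truncation matching on a logistic propensity score, and
    rank-orders every recorded ICD-9 diagnosis code by its one-year
    period-prevalence relative risk with confidence intervals and odds ratios.
    Ships a synthetic claims generator with planted per-code relative risks and
    a ground-truth manifest, so the whole pipeline is testable without access
    to proprietary claims databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
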