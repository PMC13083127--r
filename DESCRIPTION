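Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pharmacovigilance analysis toolkit for FAERS-style spontaneous
    adverse-event report databases. Reads the quarterly multi-table ASCII
    dialect (DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR), deduplicates report
    versions by the FDA rule (latest FDA_DT, ties by largest PRIMARYID),
    assembles drug + indication cohorts, and screens every (drug, preferred
    term) pair with three disproportionality algorithms: the reporting odds
    ratio, the proportional reporting ratio with Pearson chi-square, and the
    Bayesian confidence propagation neural network information component,
    each with its conventional positivity criterion. Also computes
    time-to-onset Kaplan-Meier summaries with log-rank subgroup tests,
    univariable logistic models of fatal outcome, System Organ Class
    roll-ups, stratified signal tables, and descriptive demographics, plus a
    seeded synthetic-FAERS generator with planted, recoverable structure for
    validating the whole chain offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
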