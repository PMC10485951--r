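Package: ssisentinel
Title: Semi-Automated Surveillance of Deep Surgical Site Infection After
    Colorectal Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based semi-automated surveillance of deep surgical site
    infection (SSI) after colorectal surgery from routinely collected
    electronic health record extracts. Extracts five binary surveillance
    components per surgery (prolonged stay/readmission/mortality,
    reoperation, CT radiology orders, consecutive-day systemic antibiotic
    courses, relevant-site microbiology cultures) within a 45-day
    postoperative window, combines them into high/low infection-probability
    classes under declarative rules (two published rule sets ship as
    built-ins), and scores the classifications against a chart-review
    reference standard with Wilson score confidence intervals, workload
    reduction, and Cohen's kappa for annotator agreement. A calibrated
    synthetic cohort generator realizes event-level data with planted
    component truth so the whole pipeline can be exercised without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
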