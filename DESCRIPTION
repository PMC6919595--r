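Package: qocimpact
Title: Effective Coverage and Lives-Saved Modelling for Maternal and Newborn Quality of Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links health-facility readiness surveys (SPA/SARA-style component
    checklists) to household utilization surveys (ANC4+ and facility delivery)
    to estimate baseline effective coverage of 19 antenatal, childbirth and
    postnatal interventions; builds linear scale-up trajectories capped at
    country-specific utilization; and runs a deterministic cause-specific
    mortality model to quantify maternal and neonatal lives saved and
    stillbirths prevented, with quartile-based sensitivity bounds. Includes a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
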