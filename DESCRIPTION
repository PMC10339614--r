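Package: cohortforge
Title: Harmonisation and Deterministic Linkage of Multi-Study Paediatric Rheumatology Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooling longitudinal juvenile idiopathic arthritis (JIA)
    registry extracts into a common data model: pseudonymised deterministic
    record linkage via salted one-way digests of NHS-style identifiers
    (modulus-11 validation included), per-study dialect mapping with
    granularity reduction, baseline and six-month time-point extraction,
    hierarchical person-level duplicate resolution, drug-cohort construction
    (methotrexate and TNF-inhibitor starters), and reporting of missingness,
    clinical characteristics, JADAS disease-activity scores and ACR Pedi
    response. Ships a seeded synthetic four-study cohort generator with
    planted ground truth so the whole pipeline is testable without access to
    governed patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    yaml,
    jsonlite,
    openssl,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    digest,
    withr
Config/testthat/edition: 3
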