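Package: hivcarelink
Title: Deterministic Multi-Key Record Linkage of HIV Cohort and Surveillance
    Registries with Care-Continuum Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a clinical HIV cohort registry to health-department HIV
    and STD surveillance registries with a deterministic 11-key (HIV) and
    10-key (STD) identity-matching algorithm, reconciles the matched records
    (earliest diagnosis dates, hierarchical transmission risk, fuzzy
    laboratory deduplication), and computes HIV care-continuum outcomes
    (retention in care, antiretroviral therapy, viral suppression) and
    care-site utilisation categories on the pre- and post-linkage data.
    Includes a synthetic dual-registry generator with configurable identity
    corruption and differential laboratory capture so every stage is
    verifiable against a known truth set without any real patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
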