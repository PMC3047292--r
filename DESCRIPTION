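Package: ctalert
Title: Clinical Trial Alert Recruitment Engine for General Practice Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electronic-patient-record based recruitment of general
    practice patients via clinical trial alerts (CTA): automated net-sample
    identification from age/sex inclusion rules, keyed pseudonymisation, a
    reminder-driven recruitment state machine with event-log replay, a
    synthetic practice simulator (panels, visit streams, software downtime,
    staff behaviour), recruitment-funnel and target-achievement accounting,
    demographic selection-bias quantification with chi-square contingency
    tests, registry-consistency auditing, and an adaptive reminder-suppression
    policy that counteracts detected bias. Reference tables from a 12-month
    osteoporosis-survey recruitment study across 25 German general practices
    are bundled for worked examples and regression checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    digest,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
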