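Package: sccspool
Title: Power and Days-to-Detect Planning for Pooled Self-Controlled Case
    Series Vaccine-Safety Surveillance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sample-size and surveillance-timeline planning for vaccine
    safety signal detection with the self-controlled case series (SCCS)
    design. Computes the minimal number of adverse events needed to detect
    a given relative incidence with a single post-vaccination risk window,
    turns required event counts into days of mass-vaccination throughput
    per jurisdiction and per pooled set of jurisdictions, and verifies the
    analytic power and type-I error by Monte Carlo simulation of synthetic
    case series. Ships 2021 Canadian census populations per province and
    territory (total and ages 18-39) and ready-made scenario
    configurations for myocarditis-like and VITT-like adverse events.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
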