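Package: workforcesim
Title: System-Dynamics Projection of Medical-Specialist Supply and Need
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of a specialist medical
    workforce, advanced in annual steps over age-sex cohorts for each
    specialty. Supply evolves through medical-school and residency training
    pipelines with their multi-year delays, immigration, drop-out, mortality
    and mandatory retirement; need evolves from per-100,000 normative
    standards under demand-group growth rates and population scenarios.
    Scenario objects expose every policy lever (numerus clausus, residency
    positions, retirement age, full-time-equivalent ratios, net immigration)
    as per-year schedules with carry-forward semantics, and results report
    headcount and FTE supply, need, deficit, ratios per 100,000 inhabitants
    and demographic pyramid summaries, with scenario comparison and
    single-parameter sweeps. A synthetic-data module generates calibrated,
    internally consistent input fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
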