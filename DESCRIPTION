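Package: pregepi
Title: Infer Pregnancy Episodes and Outcomes from Observational Health Data
Version: 1.0.0
Authors@R:
    person("pregepi", "developers", email = "pregepi@example.org",
           role = c("aut", "cre"))
Description: Constructs pregnancy episodes from OMOP-CDM-like patient event
    tables (person, observation_period, condition/procedure/observation/drug
    occurrences). Pregnancy outcomes (live birth, stillbirth, ectopic
    pregnancy, abortion) are classified through a sequential outcome
    hierarchy with minimum inter-outcome spacing, follow-up invalidation and
    ectopic treatment-confirmation rules; episode start dates are estimated
    from a ranked hierarchy of pregnancy markers (last menstrual period,
    gestational age records, fertility procedures, screening tests,
    amenorrhea and urine pregnancy tests) with outcome-specific average
    gestational-age fallbacks. Includes a concept-set catalog with a
    disproportionality (prevalence-ratio) screen for ectopic-associated
    codes, a synthetic claims cohort generator with planted ground truth and
    configurable billing noise, and characterization/validation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
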