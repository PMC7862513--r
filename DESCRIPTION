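Package: opatcost
Title: Payer and Provider Cost Analysis of Outpatient Parenteral Antibiotic
    Therapy for Periprosthetic Joint Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a dual-perspective (statutory health insurance payer
    versus hospital provider) cost comparison of inpatient parenteral
    antibiotic therapy (IPAT) with a simulated outpatient regimen (OPAT) for
    periprosthetic joint infection under the German DRG case-payment system.
    Implements the G-DRG case-payment arithmetic with length-of-stay trimming
    points (per-diem surcharges above the upper trim point, per-diem discounts
    below the lower one), a counterfactual early-discharge simulator driven by
    clinical-timeline criteria, outpatient costing with quarterly clinic flat
    fees, per-visit cost components and daily antibiotic rates, and ledger
    aggregation from both perspectives. Ships an embedded twelve-case hospital
    cohort with its tariff catalogue, plus a seeded synthetic-cohort generator
    so every pipeline stage is testable at arbitrary scale. All money
    arithmetic is cent-exact with half-up rounding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
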