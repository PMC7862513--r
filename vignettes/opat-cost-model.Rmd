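---
title: "The IPAT/OPAT cost model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IPAT/OPAT cost model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opatcost)
```

## The question and the accounting frame

Periprosthetic joint infection (PJI) of hip and knee endoprostheses is
typically treated with weeks of intravenous antibiotics, delivered as an
inpatient in Germany because no established outpatient parenteral
antibiotic therapy (OPAT) infrastructure exists. `opatcost` models the
counterfactual: patients who are clinically stable finish their IV course
at home with elastomeric pumps, monitored in a university outpatient
clinic. Costs are tracked from two ledgers that must not be conflated:

* **Payer** (statutory health insurance): inpatient spending *is* the
  hospital's DRG revenue; the outpatient phase adds clinic flat fees and
  prescription drug costs.
* **Provider** (hospital): fully allocated treatment cost against DRG
  revenue (the contribution margin), plus the outpatient clinic's own
  revenue-versus-cost position.

The package's embedded cohort (`pji_cohort()`) is twelve adult PJI
episodes from one university hospital's 2015 billing year, selected from
133 screening candidates by the filter in `apply_inclusion_filter()`
(minimum age 18, stay of at least 7 days, no complex-case constellations,
hip/knee prosthesis infections only, parenteral antibiotics given, no
transfer). Exclusion reasons are applied in a fixed precedence order with
first-match counting, so the tally partitions the excluded set — the
listed counts sum exactly to the number excluded, which would not hold if
a record could count under two reasons.

## DRG case payment

For a stay of `VD` days, revenue is the inlier relative weight plus one
per-day surcharge weight for each day above the upper trim point (first
surcharge day `OGVD + 1`) minus one per-day discount weight for each day
below the lower trim point (first discount day `UGVD − 1`), multiplied by
the base case value (3231.20 €/unit in 2015):

```{r}
case_revenue(84, drg_tariffs(), drg_code = "I01Z") # 34 surcharge days
per_diem_surcharge(drg_tariffs())[, c("drg_code", "surcharge_per_diem")]
```

Two numerical facts about the source tables shaped the design:

* The printed surcharge cell for I03B (255.27 €) is one cent off its own
  relative weight (0.079 × 3231.20 = 255.2648 → 255.26); the per-case
  billing table applies 255.26. The package computes, and tests against,
  the arithmetic value.
* The billed inlier revenues imply an effective base rate near 3190.81 €
  (11,116.78 / 3.484) rather than 3231.20 €, and no single rate reproduces
  every billed amount to the cent. The cohort therefore carries the billed
  `actual_revenue` (and the billed per-case surcharge per-diem and upper
  trim point, which for case 01 differ from the catalogue) as inputs;
  `case_revenue()` with an injectable `base_rate` serves as a cross-check,
  not as the source of the actuals.

**Money is half-up cents throughout** (`round_cents()`). Base R's
`round()` is round-half-to-even and disagrees with invoice arithmetic at
ties; the even-n median of the surcharge per-diems (midpoint of 245.57 and
255.26 = 250.415) must display as 250.42. Per-diem products are rounded
once per case, not per day — single multiplication reproduces every
printed cell, and day-wise rounding would differ only if rates carried
sub-cent precision, which they do not.

## The early-discharge counterfactual

The earliest simulated discharge day is the binding maximum of three
chart-review criteria: 5 days after the last operation, a dry wound
(defaulting to the admission day where wound status was never documented,
making the other criteria binding), and the day after the last medical
intervention other than plain radiography or laboratory work. Days are
indexed from admission = day 0, and the simulated day is capped at the
actual discharge. For the embedded cohort the resulting
`dischargeable_days` are inputs (the underlying timelines were never
published); synthetic cohorts regenerate them from generated timelines,
closing the loop the real cohort cannot test.

The freed bed days move money asymmetrically, which is the analytical
heart of the model:

* Payer: only surcharge days are refundable, so the revenue reduction is
  `min(saved, max(0, VD − OGVD)) × surcharge per-diem` — zero for inlier
  stays. No case may fall below its lower trim point (none does, and the
  synthetic generator never produces one).
* Provider: every saved day avoids the general-ward per-diem. Operation
  and intensive-care costs accrue before the eligibility day by
  construction and are untouched.

```{r}
summarise_simulation(simulate_discharge(pji_cohort()))
```

## OPAT costing

Outpatient duration equals the saved bed days. The payer pays a 92 € flat
fee per calendar quarter touched (eleven cases touch one, one case two)
plus the daily antibiotic cost under the pharmacy tariff. Laboratory and
radiology during OPAT are carried as explicit zero-cost line items — they
are assumed cost-neutral between settings, not forgotten. Transport,
physiotherapy and opportunity costs of re-occupied beds are out of scope,
as in the source analysis.

The reporting convention deserves a note: the per-case cost column
(duration × daily drug rate) sums to 57,395.28 €, which is reported as the
payer OPAT total, while the drug-only component is reported as that total
minus the 1,196 € clinic fees (56,199.28 €). The two published aggregates
are internally inconsistent by exactly the clinic fees; emitting both with
explicit labels reproduces each without silently preferring one.

Clinic visits cost the provider 75 € each (46 € personnel, 3 € materials,
26 € overhead). Monitoring frequency is drug-dependent: vancomycin-type
regimens require drug-level monitoring three times weekly (modelled as
`floor(days/7) × 3`), other antibiotics weekly (`ceiling(days/7)`). These
formulas are reverse-engineered from the visit-cost table and reproduce
eleven of the twelve cases; case 07 (one recorded visit over 15 days)
matches no schedule and keeps its recorded count under the `"other"`
class. Both schedules are overridable via `regimen_class`.

## Ledgers and the two benefit framings

```{r}
fit <- opat_analysis()
glance(fit)[, c("payer_net_extra_cost", "provider_net_benefit",
                "provider_net_benefit_gross", "provider_bed_days_freed")]
```

The payer's net extra cost is the OPAT total minus the inpatient saving.
On the provider side two framings circulate and both are emitted:
`net_benefit` nets the forgone DRG revenue against the saved ward cost
(deficit reduction + clinic margin), while `net_benefit_gross` compares
the residual-deficit improvement with the clinic loss without netting the
revenue side. They answer different questions — cash-flow change versus
deficit trajectory — and differ by exactly the payer's saving.

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions so that every pipeline
stage is testable at arbitrary scale: stays uniform over 19–84 days (the
cohort's range; the source reports only ranges and means, so uniform is
the least-committal choice and distributions are a config parameter), ages
63–84, daily antibiotic rates 265–570 €, the six-DRG catalogue, and half
of the stays exceeding their upper trim point (six of twelve real cases
did). Screening pools draw at most one tripped exclusion criterion per
record (multinomial over the published proportions), mirroring the
first-match partition. Case costs are built as
`stay × ward per-diem + lump`, with the operative/ICU lump placed before
the eligibility day so simulated savings depend only on ward per-diems —
setting the lump to zero lets a regression of cost on stay recover the
configured per-diem exactly, which the tests exploit. Randomness comes
from a single seed and leaves the session's RNG state untouched.

What passing synthetic tests do **not** show: the generator knows nothing
about infection courses, readmission risk, antibiotic pharmacology, or the
correlation structure of real billing data (e.g. case 01's off-catalogue
surcharge rate). It validates the *accounting*, not clinical realism.

## Numerical choices and problem sizes

* Tolerances: money comparisons are exact at cent resolution (absolute
  1e-9 after `round_cents()`).
* Degenerate inputs: zero saved days yield the identity scenario; stays of
  length `UGVD` or `OGVD` sit on the inlier plateau (the boundary day
  carries no surcharge); empty rate vectors and non-positive stays error.
* Tie-breaks: half-up rounding everywhere; even-n medians are central
  midpoints.
* Test problem sizes: the revenue oracle enumerates stays 1–60 across all
  six tariffs; ledger identities run on 100 seeded cohorts of 15 cases and
  one of 500; the screening property uses 1,330 candidates. These sizes
  give full branch coverage of the trim-point logic while keeping the
  suite fast to iterate on.

## Known limitations

The cohort is small (n = 12, one centre, one billing year) and the
discharge criteria were applied retrospectively; the package reproduces
the accounting faithfully but inherits those limits. The two off-catalogue
values of case 01 are carried verbatim and unexplained, as in the source
records. No opportunity costs, transport, or outpatient therapy
prescriptions are modelled, and the DRG engine does not group cases from
diagnoses — DRG codes are inputs.
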