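# opatcost

Dual-perspective cost analysis of **inpatient** versus simulated
**outpatient parenteral antibiotic therapy** (IPAT vs OPAT) for
periprosthetic joint infection (PJI) under the German DRG case-payment
system.

Prolonged intravenous antibiotic courses for infected hip and knee
prostheses keep patients in hospital for weeks. This package asks what
would change — for the statutory health insurer (payer) and for the
hospital (provider) — if clinically stable patients finished their IV
course at home, monitored through a university outpatient clinic. It is
aimed at health-services researchers and hospital controllers who want a
transparent, testable implementation of the underlying accounting rather
than a spreadsheet.

## The model

**DRG case payment.** A stay of length `VD` in a DRG with lower/upper
length-of-stay trim points `UGVD`/`OGVD` and relative weights is paid

```
revenue = (BR_inlier + max(0, VD − OGVD) · BR_day^OGVD
                     − max(0, UGVD − VD) · BR_day^UGVD) · BBFW
```

where `BBFW` is the federal base case value (3231.20 €/relative-weight
unit in 2015). Within the trim points the payment is a constant lump; each
day beyond the `OGVD` earns a per-diem supplement, each day short of the
`UGVD` a per-diem discount. All money is cent-exact with half-up rounding.

**Early-discharge counterfactual.** The earliest simulated discharge day is
`max(last operation + 5, last intervention + 1, wound-dry day)`, capped at
the actual discharge. The freed bed days reduce payer spending only where
they were surcharge days (`min(saved, VD − OGVD) · surcharge per-diem`) and
reduce provider cost by the general-ward per-diem for every saved day.

**OPAT costing.** The payer pays a 92 € flat fee per calendar quarter of
clinic contact plus the daily antibiotic cost (pharmacy tariff) for the
outpatient duration (= saved bed days). The provider's clinic cost is 75 €
per visit (46 personnel + 3 materials + 26 overhead); vancomycin-type
regimens need 3 monitoring visits per full week, other antibiotics 1 per
started week.

## Worked example

```r
library(opatcost)
fit <- opat_analysis()   # embedded 12-case cohort, 2015 tariff catalogue
fit
#> Dual-perspective IPAT vs simulated OPAT cost analysis
#>   cases: 12   bed days freed: 159
#>   payer:    IPAT 196260.57 EUR, savings 18117.35, OPAT 57395.28, net extra cost 39277.93
#>   provider: deficit -56022.82 -> -33426.57 EUR, clinic margin -1579.00, net benefit 21017.25
```

Reading: the 12 inpatient episodes earned the hospital 196,260.57 € in DRG
revenue against 252,283.39 € of cost, a contribution deficit of
−56,022.82 € (22 % of cost). Discharging each patient at the simulated
earliest safe day frees 159 bed days: the insurer saves 18,117.35 € of
long-stay supplements, the hospital saves 40,713.60 € of ward costs, and
the deficit shrinks to −33,426.57 €. The outpatient phase costs the payer
57,395.28 € (56,199.28 € antibiotics + 1,196 € clinic flat fees) — a net
*extra* cost of 39,277.93 € for the insurer — while the clinic runs a
small 1,579 € loss for the provider, whose overall position still improves
by 21,017.25 € (deficit reduction net of forgone revenue, minus the clinic
loss).

Per-case detail, one-row summary, and a margin plot:

```r
tidy(fit)      # per-case simulation + outpatient costing
glance(fit)    # payer_* and provider_* ledger columns in one row
autoplot(fit)  # actual vs simulated contribution margin per case
write_report(fit, "report")  # table4.csv ... table9.csv, summary.json
```

Synthetic cohorts for testing at scale:

```r
coh <- generate_cohort(generator_config(n_cases = 100, seed = 42))
opat_analysis(coh)
```

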