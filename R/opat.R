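#' Outpatient-clinic cost schedule
#'
#' The 2015 reimbursement and cost parameters of the university outpatient
#' clinic that monitors the simulated outpatient antibiotic therapy: the
#' payer reimburses a flat fee per calendar quarter covering all contacts
#' (92 EUR), while the provider's cost per visit is the sum of personnel
#' (46 EUR), materials (3 EUR) and overhead (26 EUR).
#'
#' @param quarterly_flat_fee Flat fee per calendar quarter (euros).
#' @param personnel_per_visit,materials_per_visit,overhead_per_visit
#'   Per-visit cost components (euros).
#' @return A list with the four components plus `per_visit_total`.
#' @examples
#' clinic_cost_schedule()$per_visit_total # 75
#' @export
clinic_cost_schedule <- function(quarterly_flat_fee = 92,
                                 personnel_per_visit = 46,
                                 materials_per_visit = 3,
                                 overhead_per_visit = 26) {
  stopifnot(quarterly_flat_fee > 0, personnel_per_visit >= 0,
            materials_per_visit >= 0, overhead_per_visit >= 0)
  list(
    quarterly_flat_fee = quarterly_flat_fee,
    personnel_per_visit = personnel_per_visit,
    materials_per_visit = materials_per_visit,
    overhead_per_visit = overhead_per_visit,
    per_visit_total = personnel_per_visit + materials_per_visit + overhead_per_visit
  )
}

#' Planned outpatient-clinic visit count
#'
#' Monitoring frequency depends on the antibiotic: vancomycin-type regimens
#' need drug-level monitoring three times per week (three visits per full
#' treatment week), other antibiotics once per week (one visit per started
#' week). Cases whose recorded visits match neither schedule keep their
#' recorded count (`"other"`).
#'
#' @param duration_days Outpatient treatment duration in days (vectorised).
#' @param regimen_class `"thrice_weekly"`, `"weekly"` or `"other"`.
#' @param recorded_visits Recorded visit count, used for `"other"`.
#' @return Planned visit count.
#' @examples
#' planned_visit_count(25, "thrice_weekly") # 9
#' planned_visit_count(15, "weekly")        # 3
#' @export
planned_visit_count <- function(duration_days, regimen_class,
                                recorded_visits = NA_integer_) {
  stopifnot(all(duration_days >= 0))
  n <- max(length(duration_days), length(regimen_class), length(recorded_visits))
  duration_days <- rep_len(duration_days, n)
  regimen_class <- rep_len(regimen_class, n)
  recorded_visits <- rep_len(recorded_visits, n)
  out <- dplyr::case_when(
    regimen_class == "thrice_weekly" ~ floor(duration_days / 7) * 3,
    regimen_class == "weekly" ~ ceiling(duration_days / 7),
    regimen_class == "other" ~ as.numeric(recorded_visits),
    TRUE ~ NA_real_
  )
  if (anyNA(out)) stop("unknown regimen_class or missing recorded visits", call. = FALSE)
  as.integer(out)
}

#' Per-case outpatient costing from both perspectives
#'
#' Costs the simulated outpatient phase of each case. Payer side: the
#' quarterly clinic flat fee times the quarters touched, plus the daily
#' antibiotic cost (pharmacy tariff) times the treatment duration, which
#' equals the saved bed days. Provider side: flat-fee revenue against the
#' per-visit clinic cost. Laboratory and radiology during the outpatient
#' phase are carried as explicit zero-cost line items — they are assumed
#' cost-neutral between the two settings, not omitted.
#'
#' @param cases Cohort tibble (see [pji_cohort()]); `dischargeable_days` is
#'   the outpatient treatment duration.
#' @param schedule Clinic schedule from [clinic_cost_schedule()].
#' @return A tibble per case: `case_id`, `duration_days`, `quarter_count`,
#'   `clinic_fee` (payer), `drug_daily_cost`, `drug_cost`, `lab_imaging_cost`
#'   (zero by assumption), `opat_payer_cost` (= `drug_cost`; see
#'   [payer_opat_totals()] for how fees enter the total), `visit_count`,
#'   `clinic_cost` (provider), `clinic_margin`.
#' @examples
#' cost_opat(pji_cohort())
#' @export
cost_opat <- function(cases, schedule = clinic_cost_schedule()) {
  cases <- validate_cohort(cases)
  tibble::tibble(
    case_id = cases$case_id,
    duration_days = cases$dischargeable_days,
    quarter_count = cases$quarter_count,
    clinic_fee = round_cents(cases$quarter_count * schedule$quarterly_flat_fee),
    drug_daily_cost = cases$drug_daily_cost,
    drug_cost = round_cents(cases$dischargeable_days * cases$drug_daily_cost),
    lab_imaging_cost = 0,
    opat_payer_cost = round_cents(cases$dischargeable_days * cases$drug_daily_cost),
    visit_count = cases$visit_count,
    clinic_cost = round_cents(cases$visit_count * schedule$per_visit_total),
    clinic_margin = round_cents(cases$quarter_count * schedule$quarterly_flat_fee -
                                  cases$visit_count * schedule$per_visit_total)
  )
}

#' Cohort totals of the outpatient costing
#'
#' The reporting convention follows the billed tables: the per-case cost
#' column (duration times daily drug rate) sums to the payer OPAT total,
#' and the drug-only component is reported as that total minus the clinic
#' flat fees, so that both published aggregates are reproduced.
#'
#' @param opat Per-case costing tibble from [cost_opat()].
#' @return One-row tibble: `clinic_fees`, `payer_opat_total`,
#'   `drug_component` (= total - fees), `clinic_cost`, `clinic_margin`,
#'   `visit_total`.
#' @export
payer_opat_totals <- function(opat) {
  dplyr::summarise(
    opat,
    clinic_fees = round_cents(sum(.data$clinic_fee)),
    payer_opat_total = round_cents(sum(.data$opat_payer_cost)),
    drug_component = round_cents(.data$payer_opat_total - .data$clinic_fees),
    clinic_cost = round_cents(sum(.data$clinic_cost)),
    clinic_margin = round_cents(sum(.data$clinic_margin)),
    visit_total = sum(.data$visit_count)
  )
}
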