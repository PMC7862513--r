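#' Earliest simulated discharge day
#'
#' The counterfactual earliest day a case could have switched from inpatient
#' to outpatient antibiotic therapy, from three chart-review criteria that
#' must all be satisfied: at least 5 days past the last operation, a dry
#' wound (the admission day when wound status was never documented
#' otherwise), and at least the day after the last medical intervention or
#' diagnostic procedure other than plain radiography and laboratory tests.
#' Days are indexed from admission = day 0; the result is capped at the
#' actual discharge day, since a simulated discharge cannot come later than
#' the real one.
#'
#' @param last_operation_day,last_intervention_day,wound_dry_day Event days
#'   (vectorised, day index from admission).
#' @param los Actual length of stay in days (= actual discharge day index).
#' @return Day index of the earliest simulated discharge.
#' @examples
#' earliest_discharge_day(10, 20, 12, los = 40) # 21
#' @export
earliest_discharge_day <- function(last_operation_day, last_intervention_day,
                                   wound_dry_day, los) {
  ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
  if (!ok(last_operation_day) || !ok(last_intervention_day) || !ok(wound_dry_day)) {
    stop("event days must be non-negative day indices", call. = FALSE)
  }
  if (any(last_operation_day > los) || any(last_intervention_day > los) ||
      any(wound_dry_day > los)) {
    stop("event days cannot lie beyond the actual stay", call. = FALSE)
  }
  pmin(pmax(last_operation_day + 5, last_intervention_day + 1, wound_dry_day), los)
}

#' Bed days saved by an earlier discharge
#'
#' @param los Actual length of stay in days.
#' @param discharge_day Simulated discharge day index (<= `los`).
#' @return `los - discharge_day`, the freed bed days.
#' @export
saved_days <- function(los, discharge_day) {
  if (any(discharge_day > los)) {
    stop("discharge_day cannot exceed the actual stay", call. = FALSE)
  }
  los - discharge_day
}

#' Payer revenue reduction from saved bed days
#'
#' Under DRG case payment an earlier discharge only changes the bill for
#' days above the upper trim point: each saved day that was a surcharge day
#' forgoes one per-diem supplement. Stays at or below the trim point see no
#' revenue change at all.
#'
#' @param los Actual length of stay (days).
#' @param ogvd Upper trim point applied on the bill (days).
#' @param days_saved Simulated saved bed days.
#' @param surcharge_per_diem Per-day supplement above the trim point (euros).
#' @return Euro reduction, cent-rounded; zero when `los <= ogvd`. Vectorised.
#' @examples
#' payer_revenue_reduction(40, 33, 15, 255.26) # only 7 days were billed above
#' @export
payer_revenue_reduction <- function(los, ogvd, days_saved, surcharge_per_diem) {
  check_los(los)
  if (any(days_saved < 0)) stop("days_saved must be >= 0", call. = FALSE)
  round_cents(pmin(days_saved, pmax(0, los - ogvd)) * surcharge_per_diem)
}

#' Provider cost reduction from saved bed days
#'
#' The provider saves the general-ward per-diem for every freed bed day;
#' operation and intensive-care costs are unaffected because they accrue
#' before the simulated discharge day.
#'
#' @param days_saved Simulated saved bed days.
#' @param ward_per_diem General-ward daily cost rate (euros).
#' @return Euro reduction, cent-rounded. Vectorised.
#' @export
provider_cost_reduction <- function(days_saved, ward_per_diem) {
  if (any(days_saved < 0)) stop("days_saved must be >= 0", call. = FALSE)
  round_cents(days_saved * ward_per_diem)
}

#' Simulate the early-discharge counterfactual over a cohort
#'
#' Applies the payer revenue reduction and provider cost reduction to every
#' case, using the case's billed upper trim point (`ogvd_eff`) where present
#' and the catalogue value otherwise, and derives the post-simulation
#' revenue, cost and contribution margin per case.
#'
#' @param cases Cohort tibble (see [pji_cohort()]).
#' @param tariffs Tariff catalogue resolving every `drg_code`.
#' @return A tibble with one row per case: `case_id`, `drg_code`, `los`,
#'   `ogvd`, `days_over_ogvd` (signed), `saved_days`, `revenue_reduction`,
#'   `cost_reduction`, `actual_revenue`, `new_revenue`, `actual_cost`,
#'   `new_cost`, `margin`, `new_margin`.
#' @examples
#' sim <- simulate_discharge(pji_cohort())
#' sum(sim$saved_days) # 159 freed bed days
#' @export
simulate_discharge <- function(cases, tariffs = drg_tariffs()) {
  cases <- validate_cohort(cases, tariffs = tariffs)
  tariffs <- validate_tariffs(tariffs)
  joined <- dplyr::left_join(cases,
                             dplyr::select(tariffs, "drg_code", cat_ogvd = "ogvd",
                                           cat_ugvd = "ugvd"),
                             by = "drg_code")
  ogvd <- if ("ogvd_eff" %in% names(joined)) {
    dplyr::coalesce(joined$ogvd_eff, joined$cat_ogvd)
  } else {
    joined$cat_ogvd
  }
  out <- tibble::tibble(
    case_id = joined$case_id,
    drg_code = joined$drg_code,
    los = joined$los,
    ogvd = ogvd,
    days_over_ogvd = joined$los - ogvd,
    saved_days = joined$dischargeable_days,
    revenue_reduction = payer_revenue_reduction(joined$los, ogvd,
                                                joined$dischargeable_days,
                                                joined$surcharge_per_diem),
    cost_reduction = provider_cost_reduction(joined$dischargeable_days,
                                             joined$ward_per_diem),
    actual_revenue = joined$actual_revenue,
    actual_cost = joined$actual_cost
  )
  dplyr::mutate(out,
                new_revenue = round_cents(.data$actual_revenue - .data$revenue_reduction),
                new_cost = round_cents(.data$actual_cost - .data$cost_reduction),
                margin = round_cents(.data$actual_revenue - .data$actual_cost),
                new_margin = round_cents(.data$new_revenue - .data$new_cost))
}

#' Cohort totals of the discharge simulation
#'
#' @param sim Per-case simulation tibble from [simulate_discharge()].
#' @return One-row tibble of cohort sums: saved bed days, revenue and cost
#'   reductions, actual and simulated revenue, cost and margin.
#' @export
summarise_simulation <- function(sim) {
  dplyr::summarise(
    sim,
    bed_days_saved = sum(.data$saved_days),
    revenue_reduction = round_cents(sum(.data$revenue_reduction)),
    cost_reduction = round_cents(sum(.data$cost_reduction)),
    actual_revenue = round_cents(sum(.data$actual_revenue)),
    new_revenue = round_cents(sum(.data$new_revenue)),
    actual_cost = round_cents(sum(.data$actual_cost)),
    new_cost = round_cents(sum(.data$new_cost)),
    margin = round_cents(sum(.data$margin)),
    new_margin = round_cents(sum(.data$new_margin))
  )
}
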