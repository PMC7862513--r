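#' Run the full payer/provider cost analysis
#'
#' The top-level pipeline: validates the cohort, runs the early-discharge
#' simulation ([simulate_discharge()]) and the outpatient costing
#' ([cost_opat()]), and assembles the payer and provider ledgers and the
#' per-diem summary statistics.
#'
#' @param cases Cohort tibble; defaults to the embedded twelve-case cohort.
#' @param tariffs Tariff catalogue.
#' @param schedule Outpatient-clinic cost schedule.
#' @return An object of class `opat_analysis`: a list with `cases`, `sim`
#'   (per-case simulation), `opat` (per-case outpatient costing), `payer`
#'   and `provider` ledgers (see [payer_ledger()], [provider_ledger()]),
#'   and `per_diem_stats`.
#' @examples
#' fit <- opat_analysis()
#' glance(fit)
#' @export
opat_analysis <- function(cases = pji_cohort(), tariffs = drg_tariffs(),
                          schedule = clinic_cost_schedule()) {
  cases <- validate_cohort(cases, tariffs = tariffs)
  sim <- simulate_discharge(cases, tariffs)
  sim_totals <- summarise_simulation(sim)
  opat <- cost_opat(cases, schedule)
  opat_totals <- payer_opat_totals(opat)
  structure(
    list(
      cases = cases,
      sim = sim,
      opat = opat,
      sim_totals = sim_totals,
      opat_totals = opat_totals,
      payer = payer_ledger(sim_totals, opat_totals),
      provider = provider_ledger(sim_totals, opat_totals),
      per_diem_stats = dplyr::bind_rows(
        dplyr::mutate(per_diem_statistics(cases$surcharge_per_diem),
                      rate = "inpatient_surcharge_per_diem", .before = 1),
        dplyr::mutate(per_diem_statistics(cases$drug_daily_cost),
                      rate = "outpatient_drug_daily", .before = 1)
      )
    ),
    class = "opat_analysis"
  )
}

#' Payer ledger
#'
#' From the statutory health insurer's perspective: total inpatient spending
#' equals the hospitals' DRG revenue; an earlier discharge saves the
#' surcharge per-diems above the upper trim point; the outpatient phase adds
#' clinic flat fees and antibiotic costs. The net extra cost is the
#' outpatient total minus the inpatient saving.
#'
#' @param sim_totals One-row tibble from [summarise_simulation()].
#' @param opat_totals One-row tibble from [payer_opat_totals()].
#' @return One-row tibble: `ipat_total`, `ipat_savings`, `opat_total`,
#'   `opat_drug_component`, `opat_clinic_fees`, `net_extra_cost`.
#' @export
payer_ledger <- function(sim_totals, opat_totals) {
  tibble::tibble(
    ipat_total = sim_totals$actual_revenue,
    ipat_savings = sim_totals$revenue_reduction,
    opat_total = opat_totals$payer_opat_total,
    opat_drug_component = opat_totals$drug_component,
    opat_clinic_fees = opat_totals$clinic_fees,
    net_extra_cost = round_cents(opat_totals$payer_opat_total -
                                   sim_totals$revenue_reduction)
  )
}

#' Provider ledger
#'
#' From the hospital's perspective: the actual contribution-margin deficit
#' (revenue minus cost), the simulated residual deficit after early
#' discharge, the deficit reduction, the outpatient clinic margin, and two
#' net-benefit framings that both appear in practice — `net_benefit` nets
#' the forgone DRG revenue against the saved ward costs (deficit reduction
#' plus clinic margin), while `net_benefit_gross` sets the residual-deficit
#' improvement against the clinic loss without netting the revenue side.
#'
#' @inheritParams payer_ledger
#' @return One-row tibble: `ipat_cost_total`, `ipat_revenue_total`,
#'   `deficit_actual`, `deficit_simulated`, `deficit_reduction`,
#'   `clinic_margin`, `net_benefit`, `net_benefit_gross`, `bed_days_freed`.
#' @export
provider_ledger <- function(sim_totals, opat_totals) {
  deficit_reduction <- round_cents(sim_totals$cost_reduction -
                                     sim_totals$revenue_reduction)
  tibble::tibble(
    ipat_cost_total = sim_totals$actual_cost,
    ipat_revenue_total = sim_totals$actual_revenue,
    deficit_actual = sim_totals$margin,
    deficit_simulated = sim_totals$new_margin,
    deficit_reduction = deficit_reduction,
    clinic_margin = opat_totals$clinic_margin,
    net_benefit = round_cents(deficit_reduction + opat_totals$clinic_margin),
    net_benefit_gross = round_cents(abs(sim_totals$new_margin) -
                                      abs(opat_totals$clinic_margin)),
    bed_days_freed = sim_totals$bed_days_saved
  )
}

#' Per-diem summary statistics
#'
#' Arithmetic mean, median (for even n the midpoint of the two central
#' order statistics) and min-max range of a vector of daily rates, rounded
#' half-up to cents for display.
#'
#' @param rates Numeric vector of euro per-diem rates, at least one.
#' @return One-row tibble: `n`, `mean`, `median`, `min`, `max`.
#' @examples
#' per_diem_statistics(pji_cohort()$surcharge_per_diem)
#' @export
per_diem_statistics <- function(rates) {
  if (length(rates) < 1 || !is.numeric(rates)) {
    stop("rates must be a non-empty numeric vector", call. = FALSE)
  }
  tibble::tibble(
    n = length(rates),
    mean = round_cents(mean(rates)),
    median = round_cents(stats::median(rates)),
    min = round_cents(min(rates)),
    max = round_cents(max(rates))
  )
}

# ---- methods -----------------------------------------------------------

#' @export
print.opat_analysis <- function(x, ...) {
  cat("Dual-perspective IPAT vs simulated OPAT cost analysis\n")
  cat(sprintf("  cases: %d   bed days freed: %d\n",
              nrow(x$cases), x$provider$bed_days_freed))
  cat(sprintf("  payer:    IPAT %0.2f EUR, savings %0.2f, OPAT %0.2f, net extra cost %0.2f\n",
              x$payer$ipat_total, x$payer$ipat_savings, x$payer$opat_total,
              x$payer$net_extra_cost))
  cat(sprintf("  provider: deficit %0.2f -> %0.2f EUR, clinic margin %0.2f, net benefit %0.2f\n",
              x$provider$deficit_actual, x$provider$deficit_simulated,
              x$provider$clinic_margin, x$provider$net_benefit))
  invisible(x)
}

#' Tidy the per-case ledger of an analysis
#'
#' @param x An `opat_analysis` object.
#' @param ... Unused.
#' @return A tibble with one row per case joining the discharge simulation
#'   and the outpatient costing.
#' @method tidy opat_analysis
#' @export
tidy.opat_analysis <- function(x, ...) {
  dplyr::left_join(x$sim, x$opat, by = "case_id")
}

#' One-row summary of an analysis
#'
#' @param x An `opat_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble binding the payer and provider ledgers (payer
#'   columns prefixed `payer_`, provider columns `provider_`).
#' @method glance opat_analysis
#' @export
glance.opat_analysis <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::rename_with(x$payer, ~ paste0("payer_", .x)),
    dplyr::rename_with(x$provider, ~ paste0("provider_", .x))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-case contribution margins before and after simulated discharge
#'
#' @param object An `opat_analysis` object.
#' @param ... Unused.
#' @return A ggplot: paired bars of actual and simulated contribution margin
#'   per case, hospital perspective.
#' @method autoplot opat_analysis
#' @export
autoplot.opat_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$sim, "case_id", actual = "margin", simulated = "new_margin"),
    cols = c("actual", "simulated"),
    names_to = "scenario", values_to = "margin"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case_id, y = .data$margin,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "case", y = "contribution margin (EUR)",
                  fill = NULL,
                  title = "Hospital contribution margin per case",
                  subtitle = "actual stay vs simulated early discharge") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.opat_analysis
#' @param x An `opat_analysis` object (for `plot_margins()`).
#' @export
plot_margins <- function(x, ...) autoplot.opat_analysis(x, ...)

# ---- report writing ----------------------------------------------------

#' Write the full report to disk
#'
#' Writes the per-case tables mirroring the published layout —
#' `table4.csv` (actual revenue/cost ledger), `table5.csv` (payer revenue
#' reduction), `table6.csv` (simulated hospital ledger), `table7.csv`
#' (provider cost reduction), `table8.csv` (payer outpatient costs),
#' `table9.csv` (clinic revenue vs cost) — plus `summary.json` with both
#' ledgers and the per-diem statistics, and a human-readable `summary.txt`.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param x An `opat_analysis` object.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (tables + json + txt) or `"json"` (summary only).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir, format = c("csv", "json")) {
  stopifnot(inherits(x, "opat_analysis"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_totals <- function(df, label_col = "case_id") {
    tot <- dplyr::summarise(df, dplyr::across(dplyr::where(is.numeric),
                                              ~ round_cents(sum(.x))))
    tot[[label_col]] <- "total"
    dplyr::bind_rows(df, tot)
  }
  if (format == "csv") {
    t4 <- dplyr::select(x$sim, "case_id", "drg_code", "actual_cost",
                        "actual_revenue", "margin", "los", "ogvd", "days_over_ogvd")
    t5 <- dplyr::select(x$sim, "case_id", "actual_revenue", "days_over_ogvd",
                        "saved_days", "revenue_reduction")
    t6 <- dplyr::select(x$sim, "case_id", "actual_revenue", "new_revenue",
                        "actual_cost", "new_cost", "margin", "new_margin")
    t7 <- dplyr::select(x$sim, "case_id", "actual_cost", "days_over_ogvd",
                        "saved_days", "cost_reduction")
    t8 <- dplyr::select(x$opat, "case_id", "clinic_fee", "drug_daily_cost",
                        "opat_payer_cost")
    t9 <- dplyr::select(x$opat, "case_id", "clinic_fee", "clinic_cost",
                        "clinic_margin")
    tabs <- list(table4 = t4, table5 = t5, table6 = t6, table7 = t7,
                 table8 = t8, table9 = t9)
    for (nm in names(tabs)) {
      readr::write_csv(with_totals(tabs[[nm]]), file.path(dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    writeLines(utils::capture.output(print(x)), file.path(dir, "summary.txt"))
  }
  jsonlite::write_json(
    list(payer = x$payer, provider = x$provider,
         per_diem_stats = x$per_diem_stats),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
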