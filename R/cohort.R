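#' The embedded twelve-case periprosthetic joint infection cohort
#'
#' Twelve inpatient episodes of hip/knee periprosthetic joint infection
#' treated with intravenous antibiotics at a German university hospital in
#' 2015, as billed under the G-DRG system, with all inputs the simulation
#' needs:
#'
#' * `los` — actual length of stay (days); `ogvd_eff` — the upper trim point
#'   applied on the bill for this case. For case 01 this differs from the
#'   catalogue value for its DRG (47 vs 33 days), as does its surcharge
#'   per-diem (904.74 vs 255.26 EUR); both are carried verbatim from the
#'   billing records rather than recomputed.
#' * `actual_revenue` / `actual_cost` — the DRG payment received and the
#'   provider's fully allocated treatment cost (euros).
#' * `surcharge_per_diem` — the per-day payment for days beyond `ogvd_eff`;
#'   `ward_per_diem` — the provider's general-ward daily cost rate.
#' * `dischargeable_days` — bed days after the simulated earliest safe
#'   discharge (5 days past the last operation, dry wound, day after the
#'   last non-radiology/lab intervention).
#' * `quarter_count`, `drug_daily_cost`, `visit_count`, `regimen_class` —
#'   the outpatient plan: calendar quarters touched by the outpatient phase,
#'   daily antibiotic cost under the pharmacy tariff, outpatient-clinic
#'   visits, and the monitoring schedule class (`"thrice_weekly"` for
#'   vancomycin-type regimens, `"weekly"` for other antibiotics, `"other"`
#'   where neither schedule matches the recorded visits).
#'
#' @return A tibble with 12 rows.
#' @seealso [drg_tariffs()], [simulate_discharge()], [cost_opat()]
#' @examples
#' pji_cohort()
#' @export
pji_cohort <- function() {
  tb <- tibble::tribble(
    ~case_id, ~age, ~drg_code, ~reason,                                                        ~los, ~ogvd_eff, ~actual_revenue, ~actual_cost, ~surcharge_per_diem, ~ward_per_diem, ~dischargeable_days, ~quarter_count, ~drug_daily_cost, ~visit_count, ~regimen_class,
    "01",     73L,  "I03B",    "Girdlestone situation after infected hip arthroplasty",         66L,  47L,       47539.76,        40440.18,     904.74,              271.60,         5L,                  1L,             297.18,           1L,           "weekly",
    "02",     76L,  "I12A",    "Early infection of hip arthroplasty",                           66L,  39L,       17594.41,        23541.59,     258.50,              236.56,         15L,                 1L,             265.38,           6L,           "thrice_weekly",
    "03",     65L,  "I12A",    "Late infection of knee arthroplasty",                           35L,  39L,       11116.78,        20246.01,     258.50,              257.47,         6L,                  1L,             313.55,           1L,           "weekly",
    "04",     75L,  "I04Z",    "Late infection of hip arthroplasty",                            26L,  28L,       11308.23,        13932.11,     242.34,              261.47,         4L,                  1L,             313.55,           1L,           "weekly",
    "05",     75L,  "I03B",    "Chronic late infection of hip arthroplasty",                    40L,  33L,       14754.72,        23074.57,     255.26,              305.96,         15L,                 1L,             441.43,           3L,           "weekly",
    "06",     75L,  "I12C",    "Chronic infection of knee arthroplasty",                        25L,  19L,        5721.10,        12411.70,     216.49,              230.68,         17L,                 1L,             441.43,           3L,           "weekly",
    "07",     63L,  "I12B",    "Late infection of knee arthroplasty",                           21L,  30L,        7345.24,        12662.25,     229.42,              285.93,         15L,                 2L,             568.41,           1L,           "other",
    "08",     76L,  "I01Z",    "Chronic late infection of hip arthroplasty",                    84L,  50L,       27495.16,        45209.26,     245.57,              250.33,         16L,                 1L,             265.38,           6L,           "thrice_weekly",
    "09",     73L,  "I03B",    "Girdlestone situation and osteomyelitis after infected hip arthroplasty", 19L, 33L, 11898.53,    10335.46,     255.26,              278.27,         13L,                 1L,             441.43,           2L,           "weekly",
    "10",     84L,  "I12B",    "Early infection of hip arthroplasty",                           26L,  30L,        7345.24,        16010.48,     229.42,              250.41,         14L,                 1L,             377.12,           2L,           "weekly",
    "11",     65L,  "I12A",    "Early infection of hip arthroplasty",                           22L,  39L,       11116.78,        10920.91,     258.50,              242.04,         14L,                 1L,             303.03,           2L,           "weekly",
    "12",     71L,  "I01Z",    "Chronic late infection of hip arthroplasty",                    61L,  50L,       23024.62,        23498.87,     245.57,              235.98,         25L,                 1L,             265.38,           9L,           "thrice_weekly"
  )
  validate_cohort(tb, tariffs = drg_tariffs())
}

cohort_required_cols <- c(
  "case_id", "age", "drg_code", "reason", "los", "actual_revenue",
  "actual_cost", "surcharge_per_diem", "ward_per_diem", "dischargeable_days",
  "quarter_count", "drug_daily_cost", "visit_count", "regimen_class"
)

#' Validate a cohort of case records
#'
#' Field-level invariant checks: dischargeable days within the stay, adult
#' ages, stays of at least a week, positive money amounts, a known monitoring
#' schedule class, and (when a catalogue is supplied) every DRG code
#' resolving in it. Errors name the offending field and case.
#'
#' @param cases Cohort data frame.
#' @param tariffs Optional tariff catalogue used to check `drg_code`.
#' @return The cohort as a tibble.
#' @export
validate_cohort <- function(cases, tariffs = NULL) {
  cases <- tibble::as_tibble(cases)
  missing <- setdiff(cohort_required_cols, names(cases))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(bad, field, why) {
    if (any(bad)) {
      stop("invalid '", field, "' for case(s) ",
           paste(cases$case_id[bad], collapse = ", "), ": ", why, call. = FALSE)
    }
  }
  fail(cases$age < 18, "age", "must be >= 18 for included cases")
  fail(cases$los < 7, "los", "must be >= 7 days for included cases")
  fail(cases$dischargeable_days < 0 | cases$dischargeable_days > cases$los,
       "dischargeable_days", "must lie in [0, los]")
  for (f in c("actual_revenue", "actual_cost", "surcharge_per_diem",
              "ward_per_diem", "drug_daily_cost")) {
    fail(cases[[f]] <= 0, f, "must be positive")
  }
  fail(!cases$quarter_count %in% c(1L, 2L), "quarter_count", "must be 1 or 2")
  fail(cases$visit_count < 1, "visit_count", "must be >= 1")
  fail(!cases$regimen_class %in% c("thrice_weekly", "weekly", "other"),
       "regimen_class", "must be thrice_weekly, weekly or other")
  if (!is.null(tariffs)) {
    fail(!cases$drg_code %in% tariffs$drg_code, "drg_code",
         "not present in the tariff catalogue")
  }
  cases
}

#' Read / write a cohort CSV
#'
#' The on-disk schema matches [pji_cohort()] (the `ogvd_eff` column is
#' optional; when absent the catalogue trim point is used downstream).
#' German-style decimal commas are accepted on read; files are written with
#' dot decimals in UTF-8.
#'
#' @param path File path.
#' @param tariffs Tariff catalogue used to validate DRG codes.
#' @return `load_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
load_cohort <- function(path, tariffs = drg_tariffs()) {
  money <- c("actual_revenue", "actual_cost", "surcharge_per_diem",
             "ward_per_diem", "drug_daily_cost")
  # money columns come in as text so German "11.116,78" and plain "11116.78"
  # can both be handled; readr's default locale would otherwise read the
  # decimal comma as a thousands separator
  spec <- readr::cols(case_id = readr::col_character(),
                      .default = readr::col_guess())
  for (m in money) spec$cols[[m]] <- readr::col_character()
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = spec)
  decomma <- function(x) {
    german <- grepl(",", x)
    x[german] <- gsub(",", ".", gsub("\\.", "", x[german], fixed = FALSE))
    as.numeric(x)
  }
  raw <- dplyr::mutate(raw,
                       dplyr::across(dplyr::any_of(money), decomma))
  validate_cohort(raw, tariffs = tariffs)
}

#' @rdname load_cohort
#' @param cases Cohort tibble to write.
#' @export
write_cohort <- function(cases, path) {
  readr::write_csv(tibble::as_tibble(cases), path, progress = FALSE)
  invisible(path)
}

# ---- screening ---------------------------------------------------------

exclusion_reasons <- c(
  under_18         = "Alter <18 Jahre",
  short_stay       = "Aufenthaltsdauer <7 Tage",
  complex_case     = "Komplexe Fälle",
  other_implant    = "Infektion anderer Implantate als Hüft- oder Knie-TEP",
  no_antibiotics   = "Keine Antibiotikabehandlung",
  no_infection     = "Kein Infekt",
  oral_antibiotics = "Orale Antibiotikabehandlung",
  transferred      = "Verlegung in eine andere Klinik"
)

#' Screening pool for the embedded cohort (synthetic placeholders)
#'
#' The 133 screening candidates behind the embedded cohort: the 12 included
#' cases carry their real ages and stays; the 121 excluded records are
#' synthetic placeholders that reproduce the published exclusion tally
#' (1 under 18, 33 stays under 7 days, 29 complex cases, 26 infections of
#' implants other than hip/knee prostheses, 15 without antibiotic treatment,
#' 5 without infection, 4 on oral antibiotics, 8 transferred elsewhere).
#' Individual attributes of excluded patients were never published and are
#' invented here.
#'
#' @return A tibble of screening records: `case_id`, `age`, `los`, and one
#'   logical flag column per exclusion criterion (`complex_case`,
#'   `other_implant`, `no_antibiotics`, `no_infection`, `oral_antibiotics`,
#'   `transferred`).
#' @seealso [apply_inclusion_filter()]
#' @export
screening_records <- function() {
  flags <- c("complex_case", "other_implant", "no_antibiotics",
             "no_infection", "oral_antibiotics", "transferred")
  blank <- function(n, age, los) {
    tb <- tibble::tibble(age = rep(age, length.out = n),
                         los = rep(los, length.out = n))
    for (f in flags) tb[[f]] <- FALSE
    tb
  }
  flagged <- function(n, flag) {
    tb <- blank(n, age = 60:79, los = 8:30)
    tb[[flag]] <- TRUE
    tb
  }
  included <- pji_cohort()
  pool <- dplyr::bind_rows(
    blank(12, age = included$age, los = included$los),
    blank(1, age = 15, los = 12),          # under 18
    blank(33, age = 55:75, los = 1:6),     # stay < 7 days
    flagged(29, "complex_case"),
    flagged(26, "other_implant"),
    flagged(15, "no_antibiotics"),
    flagged(5, "no_infection"),
    flagged(4, "oral_antibiotics"),
    flagged(8, "transferred")
  )
  dplyr::mutate(pool, case_id = sprintf("S%03d", dplyr::row_number()),
                .before = 1)
}

#' Apply the cohort inclusion filter
#'
#' Screens candidate records against the study criteria in a fixed
#' precedence order — age under 18, stay under 7 days, complex case,
#' infection of an implant other than a hip/knee prosthesis, no antibiotic
#' treatment, no infection, oral antibiotics, transfer to another clinic —
#' and counts each excluded record under its first matching reason, so the
#' tally partitions the excluded set.
#'
#' @param records Screening tibble as produced by [screening_records()] or
#'   [generate_screening_pool()].
#' @return A list with `included` (the surviving records), `excluded` (with
#'   an `exclusion_reason` column), and `tally` (a tibble of `reason`, `n`
#'   in precedence order, zero-count reasons retained).
#' @examples
#' apply_inclusion_filter(screening_records())$tally
#' @export
apply_inclusion_filter <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no screening records supplied", call. = FALSE)
  crit <- list(
    under_18         = records$age < 18,
    short_stay       = records$los < 7,
    complex_case     = records$complex_case,
    other_implant    = records$other_implant,
    no_antibiotics   = records$no_antibiotics,
    no_infection     = records$no_infection,
    oral_antibiotics = records$oral_antibiotics,
    transferred      = records$transferred
  )
  hit <- matrix(unlist(crit), ncol = length(crit))
  first <- apply(hit, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  reason <- unname(exclusion_reasons[names(crit)[first]])
  excluded <- dplyr::mutate(records[!is.na(first), ], exclusion_reason = reason[!is.na(first)])
  tally <- tibble::tibble(
    reason = unname(exclusion_reasons),
    n = vapply(unname(exclusion_reasons),
               function(r) sum(excluded$exclusion_reason == r), integer(1),
               USE.NAMES = FALSE)
  )
  list(included = records[is.na(first), ], excluded = excluded, tally = tally)
}
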