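#' G-DRG tariff catalogue for the embedded cohort
#'
#' The six orthopaedic revision DRGs (hip/knee prosthesis infection spectrum)
#' that cover the embedded cohort, with their 2015 length-of-stay trimming
#' points and relative weights: `ugvd`/`ogvd` are the lower/upper trim points
#' in days, `mvd` the catalogue mean stay (informational), `inlier_br` the
#' relative weight paid for any stay between the trim points, and
#' `ugvd_br`/`ogvd_br` the per-day relative weights for the discount below the
#' lower and the surcharge above the upper trim point. Multiplying a relative
#' weight by the federal base case value (`base_rate`, 3231.20 EUR in 2015)
#' yields euros.
#'
#' @return A tibble with one row per DRG and columns `drg_code`, `n_cases`,
#'   `ugvd`, `ugvd_br`, `mvd`, `inlier_br`, `ogvd`, `ogvd_br`.
#' @seealso [case_revenue()], [per_diem_surcharge()]
#' @examples
#' drg_tariffs()
#' @export
drg_tariffs <- function() {
  tb <- tibble::tribble(
    ~drg_code, ~n_cases, ~ugvd, ~ugvd_br, ~mvd, ~inlier_br, ~ogvd, ~ogvd_br,
    "I01Z",    2L,        11L,   0.326,   33.0,  6.033,      50L,   0.076,
    "I03B",    3L,         6L,   0.346,   18.5,  3.729,      33L,   0.079,
    "I04Z",    1L,         5L,   0.318,   16.2,  3.544,      28L,   0.075,
    "I12A",    3L,         7L,   0.354,   21.6,  3.484,      39L,   0.080,
    "I12B",    2L,         5L,   0.314,   15.5,  2.302,      30L,   0.071,
    "I12C",    1L,         3L,   0.293,    9.2,  1.391,      19L,   0.067
  )
  validate_tariffs(tb)
}

#' Validate a tariff catalogue
#'
#' Checks the structural invariants every catalogue row must satisfy:
#' `ugvd >= 1`, `ogvd > ugvd`, the mean stay strictly between the trim
#' points, and all relative weights positive.
#'
#' @param tariffs A data frame of tariff rows (see [drg_tariffs()] for the
#'   schema; `n_cases` is optional).
#' @return The input as a tibble, invisibly checked; errors name the
#'   offending DRG and field.
#' @export
validate_tariffs <- function(tariffs) {
  tariffs <- tibble::as_tibble(tariffs)
  needed <- c("drg_code", "ugvd", "ugvd_br", "mvd", "inlier_br", "ogvd", "ogvd_br")
  missing <- setdiff(needed, names(tariffs))
  if (length(missing) > 0) {
    stop("tariff catalogue is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check <- function(ok, field) {
    bad <- tariffs$drg_code[!ok]
    if (length(bad) > 0) {
      stop("invalid tariff field '", field, "' for DRG ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check(tariffs$ugvd >= 1, "ugvd")
  check(tariffs$ogvd > tariffs$ugvd, "ogvd")
  check(tariffs$mvd > tariffs$ugvd & tariffs$mvd < tariffs$ogvd, "mvd")
  check(tariffs$ugvd_br > 0, "ugvd_br")
  check(tariffs$inlier_br > 0, "inlier_br")
  check(tariffs$ogvd_br > 0, "ogvd_br")
  if (anyDuplicated(tariffs$drg_code)) {
    stop("duplicate drg_code in tariff catalogue", call. = FALSE)
  }
  tariffs
}

#' Read a tariff catalogue from CSV
#'
#' Comma-separated, dot-decimal, header row required; columns as in
#' [drg_tariffs()].
#'
#' @param path Path to the CSV file.
#' @return A validated tariff tibble.
#' @export
read_tariffs <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_tariffs(tb)
}

check_base_rate <- function(base_rate) {
  if (!is.numeric(base_rate) || length(base_rate) != 1 || !is.finite(base_rate) ||
      base_rate <= 0) {
    stop("base_rate must be a single positive number (euros per relative-weight unit)",
         call. = FALSE)
  }
  invisible(base_rate)
}

check_los <- function(los) {
  if (!is.numeric(los) || any(!is.finite(los)) || any(los < 1)) {
    stop("length of stay must be >= 1 day", call. = FALSE)
  }
  invisible(los)
}

#' Per-diem surcharge above the upper trim point
#'
#' The daily supplement paid for each hospital day beyond the upper trim
#' point (OGVD): the per-day relative weight times the base case value,
#' rounded half-up to cents.
#'
#' @param tariffs A tariff catalogue tibble (see [drg_tariffs()]).
#' @param base_rate Federal base case value in euros per relative-weight
#'   unit; 3231.20 EUR for 2015.
#' @return The input tibble with a `surcharge_per_diem` column appended.
#' @examples
#' per_diem_surcharge(drg_tariffs())
#' @export
per_diem_surcharge <- function(tariffs, base_rate = 3231.20) {
  tariffs <- validate_tariffs(tariffs)
  check_base_rate(base_rate)
  dplyr::mutate(tariffs,
                surcharge_per_diem = round_cents(.data$ogvd_br * base_rate))
}

#' Days billed above / below the trim points
#'
#' `surcharge_days()` counts the days beyond the upper trim point (the first
#' surcharge day is OGVD + 1); `discount_days()` counts the days short of the
#' lower trim point (the first discount day is UGVD - 1). Both are zero for
#' inlier stays.
#'
#' @param los Length of stay in days (vectorised, must be >= 1).
#' @param ogvd,ugvd Upper / lower trim point in days.
#' @return Integer-valued day counts, never negative.
#' @examples
#' surcharge_days(84, ogvd = 50) # 34
#' discount_days(4, ugvd = 6)    # 2
#' @export
surcharge_days <- function(los, ogvd) {
  check_los(los)
  pmax(0, los - ogvd)
}

#' @rdname surcharge_days
#' @export
discount_days <- function(los, ugvd) {
  check_los(los)
  pmax(0, ugvd - los)
}

#' DRG case revenue for a given length of stay
#'
#' The case payment: the inlier relative weight, plus one per-day surcharge
#' weight for every day above the upper trim point, minus one per-day
#' discount weight for every day below the lower trim point, all multiplied
#' by the base case value and rounded half-up to cents. The summed relative
#' weights form the case's effective cost weight ("Relativgewicht").
#'
#' @param los Length of stay in days (vectorised, >= 1).
#' @param tariff A single tariff row (one-row data frame) or a tariff
#'   catalogue together with `drg_code` to select the row.
#' @param base_rate Euros per relative-weight unit.
#' @param drg_code Optional DRG label used to pick a row out of a multi-row
#'   catalogue.
#' @return Euro revenue, cent-rounded, same length as `los`.
#' @examples
#' case_revenue(22, drg_tariffs(), drg_code = "I12A") # inlier payment
#' case_revenue(84, drg_tariffs(), drg_code = "I01Z") # 34 surcharge days
#' @export
case_revenue <- function(los, tariff, base_rate = 3231.20, drg_code = NULL) {
  check_los(los)
  check_base_rate(base_rate)
  tariff <- tibble::as_tibble(tariff)
  if (!is.null(drg_code)) {
    tariff <- dplyr::filter(tariff, .data$drg_code == !!drg_code)
  }
  if (nrow(tariff) != 1) {
    stop("tariff must resolve to exactly one catalogue row", call. = FALSE)
  }
  validate_tariffs(tariff)
  rw <- tariff$inlier_br +
    surcharge_days(los, tariff$ogvd) * tariff$ogvd_br -
    discount_days(los, tariff$ugvd) * tariff$ugvd_br
  round_cents(rw * base_rate)
}

#' Append computed case revenue to a cohort
#'
#' Joins each case to its catalogue row by `drg_code` and computes the DRG
#' payment from its length of stay. Intended as a cross-check column next to
#' the billed `actual_revenue`, which for real cohorts is the authoritative
#' figure.
#'
#' @param cases Cohort tibble with `drg_code` and `los` columns.
#' @param tariffs Tariff catalogue.
#' @param base_rate Euros per relative-weight unit.
#' @return `cases` with a `computed_revenue` column appended.
#' @export
add_case_revenue <- function(cases, tariffs, base_rate = 3231.20) {
  tariffs <- validate_tariffs(tariffs)
  unknown <- setdiff(unique(cases$drg_code), tariffs$drg_code)
  if (length(unknown) > 0) {
    stop("drg_code not in tariff catalogue: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(
    cases,
    dplyr::select(tariffs, "drg_code", "ugvd", "ugvd_br", "inlier_br", "ogvd", "ogvd_br"),
    by = "drg_code", suffix = c("", ".tariff")
  )
  rw <- joined$inlier_br +
    surcharge_days(joined$los, joined$ogvd) * joined$ogvd_br -
    discount_days(joined$los, joined$ugvd) * joined$ugvd_br
  out <- dplyr::mutate(cases, computed_revenue = round_cents(rw * base_rate))
  out
}
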