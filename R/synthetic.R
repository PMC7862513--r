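#' Configuration for the synthetic-cohort generator
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' embedded cohort: stays of 19-84 days, ages 63-84, the six-DRG catalogue,
#' daily antibiotic rates of 265-570 EUR, the published exclusion-reason
#' probabilities of the screening pool (121 of 133 candidates excluded),
#' and half of the generated stays exceeding their DRG's upper trim point
#' (as in the cohort, where six of twelve cases did).
#'
#' @param n_cases Number of cases (or screening candidates) to generate.
#' @param seed Integer seed; the generator is fully reproducible and leaves
#'   the session's random-number state untouched.
#' @param los_range,age_range,drug_rate_range Inclusive ranges; values are
#'   drawn uniformly (the source data reports only ranges and means, not
#'   distributions).
#' @param drg_pool Tariff catalogue to draw DRGs from.
#' @param exclusion_mix Named probabilities that a screening candidate trips
#'   each exclusion criterion (first match counts).
#' @param ogvd_straddle_fraction Probability a generated stay exceeds the
#'   upper trim point of its DRG.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_cases = 12,
                             seed = 1,
                             los_range = c(19, 84),
                             age_range = c(63, 84),
                             drug_rate_range = c(265, 570),
                             drg_pool = drg_tariffs(),
                             exclusion_mix = c(
                               under_18 = 1 / 133, short_stay = 33 / 133,
                               complex_case = 29 / 133, other_implant = 26 / 133,
                               no_antibiotics = 15 / 133, no_infection = 5 / 133,
                               oral_antibiotics = 4 / 133, transferred = 8 / 133),
                             ogvd_straddle_fraction = 0.5) {
  stopifnot(n_cases >= 1, is.numeric(seed), length(seed) == 1)
  rng <- function(r) length(r) == 2 && r[2] > r[1]
  if (!rng(los_range) || !rng(age_range) || !rng(drug_rate_range)) {
    stop("ranges must be length-2 and non-degenerate", call. = FALSE)
  }
  if (any(exclusion_mix < 0) || any(exclusion_mix > 1) || sum(exclusion_mix) > 1) {
    stop("exclusion_mix entries must be probabilities summing to at most 1",
         call. = FALSE)
  }
  if (ogvd_straddle_fraction < 0 || ogvd_straddle_fraction > 1) {
    stop("ogvd_straddle_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         los_range = los_range, age_range = age_range,
         drug_rate_range = drug_rate_range,
         drg_pool = validate_tariffs(drg_pool),
         exclusion_mix = exclusion_mix,
         ogvd_straddle_fraction = ogvd_straddle_fraction),
    class = "generator_config"
  )
}

#' Generate a synthetic screening pool
#'
#' Draws screening candidates whose exclusion-reason proportions follow
#' `cfg$exclusion_mix` in expectation: each record is assigned at most one
#' tripped criterion (multinomial over the mix plus the inclusion
#' remainder), mirroring the first-match partition of the real tally.
#' Under-18 and short-stay records get ages/stays that trip those criteria;
#' all others get admissible ages and stays.
#'
#' @param cfg A [generator_config()].
#' @return A screening tibble with the same columns as
#'   [screening_records()].
#' @export
generate_screening_pool <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cases
    reasons <- c(names(cfg$exclusion_mix), "included")
    p <- c(cfg$exclusion_mix, included = 1 - sum(cfg$exclusion_mix))
    pick <- sample(reasons, n, replace = TRUE, prob = p)
    age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
    los <- sample(seq(max(7, cfg$los_range[1]), cfg$los_range[2]), n, replace = TRUE)
    age[pick == "under_18"] <- sample(8:17, sum(pick == "under_18"), replace = TRUE)
    los[pick == "short_stay"] <- sample(1:6, sum(pick == "short_stay"), replace = TRUE)
    tb <- tibble::tibble(
      case_id = sprintf("G%04d", seq_len(n)),
      age = age, los = los,
      complex_case = pick == "complex_case",
      other_implant = pick == "other_implant",
      no_antibiotics = pick == "no_antibiotics",
      no_infection = pick == "no_infection",
      oral_antibiotics = pick == "oral_antibiotics",
      transferred = pick == "transferred"
    )
    tb
  })
}

#' Generate a synthetic cohort with clinical timelines
#'
#' Builds cases the whole pipeline can run on, closing the loop the real
#' cohort cannot test: each case gets a clinical timeline (last operation,
#' last intervention, wound-dry day), its `dischargeable_days` are computed
#' from that timeline via [earliest_discharge_day()], the ward per-diem and
#' a case-specific lump for operations/intensive care (placed before the
#' eligibility day) build `actual_cost`, and `actual_revenue` and the
#' surcharge per-diem come from the DRG catalogue via [case_revenue()] and
#' [per_diem_surcharge()]. Stays exceed the upper trim point with
#' probability `ogvd_straddle_fraction` and never undercut the lower one.
#'
#' @param cfg A [generator_config()].
#' @param base_rate Euros per relative-weight unit for revenue calculation.
#' @param lump_range Range of the case-specific lump cost (euros) for
#'   operations and intensive care; set `c(0, 0)` to make cost a pure
#'   per-diem multiple.
#' @param ward_per_diem_range Range of the general-ward daily cost rate.
#' @return A cohort tibble with the [pji_cohort()] columns plus the
#'   timeline columns `last_operation_day`, `last_intervention_day`,
#'   `wound_dry_day` and `lump_cost`.
#' @examples
#' coh <- generate_cohort(generator_config(n_cases = 5, seed = 42))
#' simulate_discharge(coh)
#' @export
generate_cohort <- function(cfg, base_rate = 3231.20,
                            lump_range = c(2000, 15000),
                            ward_per_diem_range = c(216, 306)) {
  stopifnot(inherits(cfg, "generator_config"))
  tariffs <- per_diem_surcharge(cfg$drg_pool, base_rate)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cases
    rows <- tariffs[sample.int(nrow(tariffs), n, replace = TRUE), ]
    straddle <- stats::runif(n) < cfg$ogvd_straddle_fraction
    lo <- pmax(cfg$los_range[1], rows$ugvd)            # never undercut the UGVD
    hi <- pmax(cfg$los_range[2], rows$ogvd + 2)
    los <- integer(n)
    for (i in seq_len(n)) {
      pool <- if (straddle[i]) {
        seq(rows$ogvd[i] + 1, hi[i])
      } else {
        seq(lo[i], max(lo[i], min(rows$ogvd[i], cfg$los_range[2])))
      }
      los[i] <- if (length(pool) == 1) pool else sample(pool, 1)
    }
    # timeline: last operation in the first half of the stay, last
    # intervention between operation and discharge, wound dry shortly after
    # the operation (admission day when undocumented)
    op <- vapply(los, function(l) sample.int(max(1, l %/% 2), 1), integer(1))
    iv <- vapply(seq_len(n), function(i) {
      sample(seq(op[i], los[i]), 1)
    }, integer(1))
    wd <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.3) 0L else min(op[i] + sample(2:6, 1), los[i])
    }, integer(1))
    eligible <- earliest_discharge_day(op, iv, wd, los)
    ward <- round_cents(stats::runif(n, ward_per_diem_range[1], ward_per_diem_range[2]))
    lump <- round_cents(stats::runif(n, lump_range[1], lump_range[2]))
    drug <- round_cents(stats::runif(n, cfg$drug_rate_range[1], cfg$drug_rate_range[2]))
    regimen <- sample(c("thrice_weekly", "weekly"), n, replace = TRUE,
                      prob = c(0.25, 0.75))
    duration <- los - eligible
    # quarters overlapped by the outpatient interval: uniform start date in
    # the year, duration days long
    start <- sample.int(365, n, replace = TRUE)
    qtr <- function(doy) (pmin(doy, 365) - 1) %/% 92 + 1
    quarters <- pmin(2L, qtr(start + pmax(duration, 1) - 1) - qtr(start) + 1L)
    revenue <- vapply(seq_len(n), function(i) {
      case_revenue(los[i], rows[i, ], base_rate)
    }, numeric(1))
    tb <- tibble::tibble(
      case_id = sprintf("C%04d", seq_len(n)),
      age = sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE),
      drg_code = rows$drg_code,
      reason = "synthetic prosthetic joint infection episode",
      los = los,
      actual_revenue = revenue,
      actual_cost = round_cents(los * ward + lump),
      surcharge_per_diem = rows$surcharge_per_diem,
      ward_per_diem = ward,
      dischargeable_days = duration,
      quarter_count = as.integer(quarters),
      drug_daily_cost = drug,
      visit_count = planned_visit_count(pmax(duration, 1), regimen),
      regimen_class = regimen,
      last_operation_day = op,
      last_intervention_day = iv,
      wound_dry_day = wd,
      lump_cost = lump
    )
    tb$visit_count <- pmax(tb$visit_count, 1L)
    validate_cohort(tb, tariffs = cfg$drg_pool)
  })
}
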