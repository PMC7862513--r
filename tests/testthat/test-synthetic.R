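test_that("generator is deterministic under a fixed seed and leaves RNG state alone", {
  cfg <- generator_config(n_cases = 40, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  p1 <- generate_screening_pool(cfg)
  p2 <- generate_screening_pool(cfg)
  expect_identical(p1, p2)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(generator_config(n_cases = 5, seed = 99)))
  expect_identical(runif(1), before)
})

test_that("generator config rejects invalid study conditions", {
  expect_error(generator_config(n_cases = 0), "n_cases")
  expect_error(generator_config(los_range = c(30, 30)), "non-degenerate")
  expect_error(generator_config(exclusion_mix = c(short_stay = 1.2)), "probabilities")
  expect_error(generator_config(ogvd_straddle_fraction = 2), "straddle")
})

test_that("screening pool inclusion fraction tracks the configured mix", {
  cfg <- generator_config(n_cases = 1330, seed = 11)
  pool <- generate_screening_pool(cfg)
  res <- apply_inclusion_filter(pool)
  p_incl <- 1 - sum(cfg$exclusion_mix) # 12/133
  # binomial 99.9% band around the expected inclusion count
  band <- qbinom(c(5e-4, 1 - 5e-4), 1330, p_incl)
  expect_gte(nrow(res$included), band[1])
  expect_lte(nrow(res$included), band[2])
  # all-zero mix includes everyone
  all_in <- generate_screening_pool(generator_config(
    n_cases = 50, seed = 2,
    exclusion_mix = c(short_stay = 0, under_18 = 0)))
  expect_equal(nrow(apply_inclusion_filter(all_in)$included), 50)
})

test_that("generated cases close the timeline loop by construction", {
  coh <- generate_cohort(generator_config(n_cases = 200, seed = 3))
  eligible <- earliest_discharge_day(coh$last_operation_day,
                                     coh$last_intervention_day,
                                     coh$wound_dry_day, coh$los)
  expect_equal(coh$dischargeable_days, coh$los - eligible)
  expect_silent(validate_cohort(coh, tariffs = drg_tariffs()))
})

test_that("never-straddling cohorts see no payer revenue reduction", {
  coh <- generate_cohort(generator_config(n_cases = 60, seed = 5,
                                          ogvd_straddle_fraction = 0))
  sim <- simulate_discharge(coh)
  expect_true(all(sim$revenue_reduction == 0))
  expect_true(all(sim$days_over_ogvd <= 0))
})

test_that("pipeline totals equal independent per-case brute-force summation", {
  coh <- generate_cohort(generator_config(n_cases = 500, seed = 17))
  fit <- opat_analysis(coh)
  # independent accumulation, case by case, straight from the cohort columns
  by_hand <- list(rev_red = 0, cost_red = 0, opat = 0, fees = 0, clinic = 0)
  tariffs <- drg_tariffs()
  for (i in seq_len(nrow(coh))) {
    r <- coh[i, ]
    over <- max(0, r$los - tariffs$ogvd[tariffs$drg_code == r$drg_code])
    by_hand$rev_red <- by_hand$rev_red +
      round_cents(min(r$dischargeable_days, over) * r$surcharge_per_diem)
    by_hand$cost_red <- by_hand$cost_red +
      round_cents(r$dischargeable_days * r$ward_per_diem)
    by_hand$opat <- by_hand$opat +
      round_cents(r$dischargeable_days * r$drug_daily_cost)
    by_hand$fees <- by_hand$fees + 92 * r$quarter_count
    by_hand$clinic <- by_hand$clinic + 92 * r$quarter_count - 75 * r$visit_count
  }
  expect_cents(fit$payer$ipat_savings, by_hand$rev_red)
  expect_cents(fit$sim_totals$cost_reduction, by_hand$cost_red)
  expect_cents(fit$payer$opat_total, by_hand$opat)
  expect_cents(fit$payer$opat_clinic_fees, by_hand$fees)
  expect_cents(fit$provider$clinic_margin, by_hand$clinic)
})

test_that("with fixed ward per-diem and no lump costs, regression recovers the rate", {
  coh <- generate_cohort(generator_config(n_cases = 80, seed = 21),
                         lump_range = c(0, 0),
                         ward_per_diem_range = c(250, 250 + 1e-9))
  fit <- lm(actual_cost ~ 0 + los, data = coh)
  expect_equal(unname(coef(fit)["los"]), 250, tolerance = 1e-9)
})
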