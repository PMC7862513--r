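test_that("earliest discharge day is the binding maximum of the three criteria", {
  # brute force over the criteria: first day all three are satisfied
  brute <- function(op, iv, wd, los) {
    ok <- vapply(0:los, function(d) d >= op + 5 && d >= iv + 1 && d >= wd, logical(1))
    if (any(ok)) min((0:los)[ok]) else los
  }
  cases <- list(c(10, 20, 12, 40), c(0, 0, 0, 30), c(5, 3, 9, 25),
                c(20, 5, 0, 22), c(3, 21, 4, 22))
  for (cs in cases) {
    expect_equal(earliest_discharge_day(cs[1], cs[2], cs[3], cs[4]),
                 brute(cs[1], cs[2], cs[3], cs[4]))
  }
  expect_equal(earliest_discharge_day(10, 20, 12, 40), 21)
  expect_equal(earliest_discharge_day(0, 0, 0, 30), 5) # operation + 5 dominates
  # operation two days before actual discharge: capped at the actual stay
  expect_equal(earliest_discharge_day(38, 0, 0, 40), 40)
  expect_error(earliest_discharge_day(50, 0, 0, 40), "beyond the actual stay")
})

test_that("saved days count freed bed days", {
  expect_equal(saved_days(61, 36), 25)
  expect_equal(saved_days(30, 30), 0)
  expect_error(saved_days(30, 31), "exceed")
})

test_that("payer revenue reduction only touches days billed above the trim point", {
  expect_cents(payer_revenue_reduction(40, 33, 15, 255.26), 1786.82) # 7 surcharge days bind
  expect_cents(payer_revenue_reduction(66, 47, 5, 904.74), 4523.70)  # saved days bind
  expect_cents(payer_revenue_reduction(35, 39, 6, 258.50), 0)        # inlier stay: nothing
  expect_cents(payer_revenue_reduction(25, 19, 17, 216.49), 1298.94)
  # bounded by both saved days and surcharge days
  expect_lte(payer_revenue_reduction(66, 39, 15, 258.50), 15 * 258.50)
  expect_lte(payer_revenue_reduction(66, 39, 15, 258.50), 27 * 258.50)
})

test_that("provider cost reduction is saved days times the ward per-diem", {
  expect_cents(provider_cost_reduction(5, 271.60), 1358.00)
  expect_cents(provider_cost_reduction(15, 236.56), 3548.40)
  expect_cents(provider_cost_reduction(0, 300), 0)
})

test_that("cohort simulation reproduces the per-case and total ledgers", {
  sim <- simulate_discharge(pji_cohort())
  tot <- summarise_simulation(sim)
  c01 <- sim[sim$case_id == "01", ]
  expect_cents(c01$new_revenue, 43016.06)
  expect_cents(c01$new_cost, 39082.18)
  expect_cents(c01$new_margin, 3933.88)
  c12 <- sim[sim$case_id == "12", ]
  expect_cents(c12$cost_reduction, 5899.50)
  expect_cents(c12$revenue_reduction, 2701.27)
  expect_equal(tot$bed_days_saved, 159)
  expect_cents(tot$revenue_reduction, 18117.35)
  expect_cents(tot$cost_reduction, 40713.60)
  expect_cents(tot$new_revenue, 178143.22)
  expect_cents(tot$new_cost, 211569.79)
  expect_cents(tot$new_margin, -33426.57)
  # conservation identities
  expect_cents(tot$new_revenue, tot$actual_revenue - tot$revenue_reduction)
  expect_cents(tot$new_cost, tot$actual_cost - tot$cost_reduction)
  expect_cents(sim$new_margin, sim$new_revenue - sim$new_cost)
})

test_that("zero saved days reduce nothing and more saved days never raise anything", {
  frozen <- dplyr::mutate(pji_cohort(), dischargeable_days = 0L)
  sim0 <- simulate_discharge(frozen)
  expect_equal(sim0$new_revenue, sim0$actual_revenue)
  expect_equal(sim0$new_cost, sim0$actual_cost)
  base <- simulate_discharge(pji_cohort())
  bumped <- dplyr::mutate(pji_cohort(),
                          dischargeable_days = pmin(los, dischargeable_days + 3L))
  sim2 <- simulate_discharge(bumped)
  expect_true(all(sim2$new_cost <= base$new_cost + 1e-9))
  expect_true(all(sim2$new_revenue <= base$new_revenue + 1e-9))
})

test_that("no fixture case falls below its lower trim point after simulated discharge", {
  sim <- simulate_discharge(pji_cohort())
  ugvd <- drg_tariffs()$ugvd[match(sim$drg_code, drg_tariffs()$drg_code)]
  expect_true(all(sim$los - sim$saved_days >= ugvd))
})
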