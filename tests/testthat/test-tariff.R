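test_that("half-up cent rounding behaves commercially at ties and signs", {
  expect_equal(round_cents(250.415), 250.42)
  expect_equal(round_cents(-250.415), -250.42)
  expect_equal(round_cents(0.079 * 3231.20), 255.26)
  expect_equal(round_cents(c(1.004, 1.005, 1.0049)), c(1.00, 1.01, 1.00))
  expect_equal(round_cents(1234.5, digits = 0), 1235)
})

test_that("per-diem surcharge reproduces the 2015 catalogue cells", {
  ze <- per_diem_surcharge(drg_tariffs(), base_rate = 3231.20)
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I01Z"], 245.57)
  # the catalogue print for I03B (255.27) is off by a cent from its own
  # relative weight; the per-case tables use the arithmetic value 255.26
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I03B"], 255.26)
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I04Z"], 242.34)
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I12A"], 258.50)
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I12B"], 229.42)
  expect_equal(ze$surcharge_per_diem[ze$drg_code == "I12C"], 216.49)
  expect_error(per_diem_surcharge(drg_tariffs(), base_rate = 0), "base_rate")
})

test_that("surcharge and discount day counts follow the trim-point rules", {
  i01z <- dplyr::filter(drg_tariffs(), drg_code == "I01Z")
  expect_equal(surcharge_days(84, i01z$ogvd), 34)
  expect_equal(surcharge_days(35, 39), 0)
  expect_equal(surcharge_days(50, i01z$ogvd), 0) # day at the bound: no supplement
  expect_equal(discount_days(11, i01z$ugvd), 0)  # stay at the lower bound: inlier
  expect_equal(discount_days(10, i01z$ugvd), 1)  # first discount day is UGVD - 1
  expect_equal(discount_days(8, i01z$ugvd), 3)
  expect_error(surcharge_days(0, 50), "length of stay")
  expect_error(discount_days(-1, 11), "length of stay")
})

test_that("case revenue matches the printed inlier payments at the implied base rate", {
  # both I12A inlier stays (35 and 22 days) billed identically; the revenue
  # column implies an effective base rate of 11116.78 / 3.484
  eff_rate <- 11116.78 / 3.484
  i12a <- dplyr::filter(drg_tariffs(), drg_code == "I12A")
  expect_equal(case_revenue(22, i12a, base_rate = eff_rate), 11116.78)
  expect_equal(case_revenue(35, i12a, base_rate = eff_rate),
               case_revenue(22, i12a, base_rate = eff_rate))
  # stay at the lower trim point: pure inlier weight times the base rate
  expect_equal(case_revenue(7, i12a, base_rate = 3231.20),
               round_cents(3.484 * 3231.20))
})

test_that("case revenue equals brute-force day accumulation over los 1-60 and all tariffs", {
  tariffs <- drg_tariffs()
  for (i in seq_len(nrow(tariffs))) {
    trf <- tariffs[i, ]
    expected <- vapply(1:60, brute_force_revenue, numeric(1),
                       tariff = trf, base_rate = 3231.20)
    got <- vapply(1:60, case_revenue, numeric(1),
                  tariff = trf, base_rate = 3231.20)
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("revenue is non-decreasing in los with a constant inlier plateau", {
  for (i in seq_len(nrow(drg_tariffs()))) {
    trf <- drg_tariffs()[i, ]
    rev <- vapply(1:70, case_revenue, numeric(1), tariff = trf)
    expect_true(all(diff(rev) >= -1e-9))
    plateau <- rev[seq(trf$ugvd, trf$ogvd)]
    expect_equal(max(plateau) - min(plateau), 0)
  }
})

test_that("tariff validation rejects broken catalogues and reads CSV", {
  bad <- drg_tariffs()
  bad$ogvd[1] <- bad$ugvd[1] # upper bound not above lower
  expect_error(validate_tariffs(bad), "ogvd")
  bad2 <- drg_tariffs()
  bad2$inlier_br[2] <- 0
  expect_error(validate_tariffs(bad2), "inlier_br")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(drg_tariffs(), path)
  expect_equal(read_tariffs(path), drg_tariffs())
})
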