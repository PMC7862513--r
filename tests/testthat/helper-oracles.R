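# Brute-force day-by-day accumulation of a DRG case payment, independent of
# the closed-form in case_revenue(): the inlier lump, one surcharge weight
# per enumerated day above the upper trim point, one discount weight per
# enumerated day from UGVD-1 down to the admission-adjacent day.
brute_force_revenue <- function(los, tariff, base_rate) {
  rw <- tariff$inlier_br
  for (d in seq_len(los)) {
    if (d > tariff$ogvd) rw <- rw + tariff$ogvd_br
  }
  if (los <= tariff$ugvd - 1) {
    for (d in seq(from = tariff$ugvd - 1, to = los, by = -1)) {
      rw <- rw - tariff$ugvd_br
    }
  }
  round_cents(rw * base_rate)
}

expect_cents <- function(object, expected) {
  expect_equal(round_cents(object), round_cents(expected), tolerance = 1e-9)
}
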