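#' Round money half-up
#'
#' Commercial (half-up) rounding to a fixed number of decimal places, the
#' convention used on German hospital invoices: exactly half a cent always
#' rounds away from zero. Base R's `round()` rounds half to even, which
#' disagrees with printed tariff tables at ties (e.g. a per-diem midpoint of
#' 250.415 EUR must display as 250.42, not 250.41).
#'
#' @param x Numeric vector of euro amounts.
#' @param digits Decimal places to keep (default 2, i.e. cents).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_cents(0.079 * 3231.20) # 255.26
#' round_cents(250.415)         # 250.42
#' @export
round_cents <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # epsilon guards against binary representations sitting a hair below .5
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# cent-exact equality for internal checks
cents_equal <- function(x, y) {
  isTRUE(all(abs(round_cents(x) - round_cents(y)) < 1e-9))
}
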