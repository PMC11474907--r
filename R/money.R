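#' Convert US dollars to integer cents
#'
#' Money is carried internally as fixed-point integer cents so that the
#' component-sum identity of a cost breakdown (total = human resources +
#' space/equipment + indirects + consumables) holds exactly, with no binary
#' floating-point residue. Rounding to the cent grid uses [round()], i.e.
#' half-even ("banker's") rounding.
#'
#' @param x numeric vector of dollar amounts.
#' @return integer vector of cents.
#' @examples
#' usd_cents(8.18)      # 818L
#' cents_usd(usd_cents(c(1.005, 2.015)))
#' @export
usd_cents <- function(x) {
  if (!is.numeric(x)) abort_validation("money amounts must be numeric")
  as.integer(round(x * 100))
}

#' @rdname usd_cents
#' @param cents integer vector of cents.
#' @export
cents_usd <- function(cents) cents / 100

# Snap a dollar amount to the cent grid.
round_money <- function(x) cents_usd(usd_cents(x))

fmt_usd <- function(x) sprintf("%.2f", x)
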