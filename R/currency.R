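#' Exchange-rate table
#'
#' Holds a base currency and the number of units of each foreign currency per
#' one unit of the base. The default table encodes the World Bank 2016 annual
#' rates used for the Uzbekistan shipment study setting:
#' 1 EUR = 1.107 USD = 3282 UZS.
#'
#' @param base Base currency code (ISO 4217 style), default `"EUR"`.
#' @param rates Named numeric vector: units of that currency per 1 unit of
#'   base. The base itself is always present with rate 1.
#' @return An object of class `currency_table`.
#' @examples
#' ct <- currency_table()
#' convert_currency(1.107, "USD", ct) # 1 EUR
#' @export
currency_table <- function(base = "EUR", rates = c(USD = 1.107, UZS = 3282)) {
  stopifnot(is.character(base), length(base) == 1L, nzchar(base))
  rates <- rates[setdiff(names(rates), base)]
  if (length(rates) && (is.null(names(rates)) || any(!nzchar(names(rates)))))
    stop("all exchange rates must be named by currency code")
  rates <- c(stats::setNames(1, base), rates)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("exchange rates must be finite and strictly positive")
  structure(list(base = base, rates = rates), class = "currency_table")
}

#' @export
print.currency_table <- function(x, ...) {
  cat("<currency_table> base:", x$base, "\n")
  for (code in names(x$rates))
    cat(sprintf("  1 %s = %g %s\n", x$base, x$rates[[code]], code))
  invisible(x)
}

#' Convert an amount to the base currency
#'
#' @param amount Numeric amount(s) in the currency `from`.
#' @param from Currency code(s), recycled against `amount`.
#' @param table A [currency_table()].
#' @return Amount(s) in the table's base currency.
#' @examples
#' convert_currency(3282, "UZS", currency_table()) # 1 EUR
#' @export
convert_currency <- function(amount, from, table) {
  stopifnot(inherits(table, "currency_table"), is.numeric(amount))
  unknown <- setdiff(unique(from), names(table$rates))
  if (length(unknown))
    stop("unknown currency code: ", paste(unknown, collapse = ", "))
  amount / unname(table$rates[from])
}

#' Money amount tagged with a currency
#'
#' A minimal container pairing an amount with its currency code, used where
#' shipment-level inputs (land freight, customs fee) may arrive in a foreign
#' currency before conversion.
#'
#' @param amount Single non-negative finite number.
#' @param currency Currency code, default `"EUR"`.
#' @return A list of class `money` with elements `amount` and `currency`.
#' @export
money <- function(amount, currency = "EUR") {
  stopifnot(is.numeric(amount), length(amount) == 1L, is.finite(amount))
  structure(list(amount = as.numeric(amount), currency = currency),
            class = "money")
}

#' @export
print.money <- function(x, ...) {
  cat(sprintf("%s %g\n", x$currency, x$amount))
  invisible(x)
}

# Coerce a money object (or bare number, taken as base currency) to a base
# currency scalar.
to_base <- function(x, table) {
  if (inherits(x, "money")) convert_currency(x$amount, x$currency, table)
  else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
  else stop("expected a money() object or a single number")
}
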