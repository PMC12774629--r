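#' Round half-up
#'
#' Commercial rounding: ties go away from zero (0.5 -> 1), unlike base
#' [round()] which rounds half to even. Used everywhere a monetary amount or
#' ratio is rounded for display, because published SROI tables use half-up
#' rounding to whole currency units.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (default 0).
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.5)       # 1
#' round_half_up(2.5)       # 3, where round() gives 2
#' round_half_up(5.1753, 2) # 5.18
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L)
  p <- 10^digits
  # nudge by machine epsilon scaled to x so that values which are exactly
  # .5 after an inexact decimal computation still round up
  z <- abs(x) * p
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps) * z)
  sign(x) * z / p
}

#' Monetary amounts with a currency tag
#'
#' A thin numeric class carrying an ISO currency code. Arithmetic between two
#' `money` values requires matching currencies; conversion is only possible
#' through an explicit [currency_table()]. Scaling by plain numbers is
#' allowed. Amounts must be finite.
#'
#' @param amount finite numeric vector.
#' @param currency single ISO currency code (default `"GBP"`, the base
#'   currency of the analysis).
#' @return a `money` object (numeric with a `currency` attribute).
#' @examples
#' money(189498) + money(1)
#' money(100) * 2
#' @export
money <- function(amount, currency = "GBP") {
  stopifnot(is.numeric(amount), is.character(currency), length(currency) == 1L)
  if (any(!is.finite(amount))) {
    stop("money amounts must be finite", call. = FALSE)
  }
  structure(as.numeric(amount), class = "money", currency = currency)
}

#' @export
currency <- function(x) UseMethod("currency")

#' @export
currency.money <- function(x) attr(x, "currency")

#' @export
format.money <- function(x, ...) {
  paste0(
    attr(x, "currency"), " ",
    formatC(unclass(x), format = "f", digits = 2, big.mark = ",")
  )
}

#' @export
print.money <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
Ops.money <- function(e1, e2) {
  if (missing(e2)) {
    return(money(get(.Generic)(unclass(e1)), attr(e1, "currency")))
  }
  m1 <- inherits(e1, "money")
  m2 <- inherits(e2, "money")
  if (m1 && m2) {
    if (!identical(attr(e1, "currency"), attr(e2, "currency"))) {
      stop(sprintf(
        "money arithmetic requires matching currencies (%s vs %s); use convert()",
        attr(e1, "currency"), attr(e2, "currency")
      ), call. = FALSE)
    }
    cur <- attr(e1, "currency")
  } else {
    cur <- if (m1) attr(e1, "currency") else attr(e2, "currency")
  }
  out <- get(.Generic)(unclass(e1), unclass(e2))
  if (.Generic %in% c("+", "-", "*", "/")) money(out, cur) else out
}

#' @export
as.numeric.money <- function(x, ...) unclass(x)

#' Currency conversion table
#'
#' A named vector of multipliers per 1 GBP. GBP itself must map to exactly 1
#' and every rate must be positive.
#'
#' @param rates named numeric vector, e.g. `c(GBP = 1, USD = 1.474)`.
#' @return a `currency_table` object.
#' @export
currency_table <- function(rates = c(GBP = 1)) {
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  if (!"GBP" %in% names(rates)) rates <- c(GBP = 1, rates)
  if (any(rates <= 0) || any(!is.finite(rates))) {
    stop("all currency rates must be finite and > 0", call. = FALSE)
  }
  if (rates[["GBP"]] != 1) {
    stop("the GBP rate must be exactly 1 (GBP is the base currency)", call. = FALSE)
  }
  structure(rates, class = "currency_table")
}

#' Convert a monetary amount to another currency
#'
#' Multiplies a GBP-based amount by the table rate for the target currency
#' and rounds half-up to whole currency units (matching how published SROI
#' tables print converted values).
#'
#' @param amount a [money()] value or plain numeric treated as GBP.
#' @param to target ISO currency code.
#' @param table a [currency_table()].
#' @param digits decimal places kept after conversion (default 0, whole units).
#' @return a `money` value in the target currency.
#' @examples
#' tbl <- currency_table(c(GBP = 1, USD = 1.4740, EUR = 1.3580))
#' convert(money(189498), "USD", tbl)
#' @export
convert <- function(amount, to, table, digits = 0) {
  stopifnot(inherits(table, "currency_table"), length(to) == 1L)
  if (!inherits(amount, "money")) amount <- money(amount)
  from <- attr(amount, "currency")
  if (!from %in% names(table)) {
    stop(sprintf("unknown source currency '%s'", from), call. = FALSE)
  }
  if (!to %in% names(table)) {
    stop(sprintf("unknown target currency '%s'", to), call. = FALSE)
  }
  gbp <- unclass(amount) / table[[from]]
  money(round_half_up(gbp * table[[to]], digits), to)
}
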