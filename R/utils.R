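`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounding used throughout the weight-derivation rule. Unlike [base::round()]
#' (banker's rounding), exact halves move away from zero, so `0.5 -> 1` and
#' `-0.5 -> -1`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as numeric).
#' @export
#' @examples
#' round_half_away(c(0.5, -0.5, 1.49, 1.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Convert a Cox regression coefficient to an integer score weight
#'
#' Implements the divide-and-round rule used to build the index: the log
#' hazard ratio is divided by `divisor` (0.3 by default) and rounded to the
#' nearest integer, halves away from zero.
#'
#' @param coefficient Numeric vector of log hazard ratios.
#' @param divisor Positive scale divisor; default 0.3.
#' @return Integer vector of weights.
#' @export
#' @examples
#' weight_from_coefficient(c(1.672, -0.560, 0.087))
weight_from_coefficient <- function(coefficient, divisor = 0.3) {
  stopifnot(is.numeric(coefficient), divisor > 0)
  as.integer(round_half_away(coefficient / divisor))
}

# internal: parse ISO dates strictly, NA allowed
parse_iso_date <- function(x) {
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x)
  if (any(ok)) {
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    out[ok] <- parsed
  }
  out
}

# days between two Dates as integer
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

DAYS_PER_YEAR <- 365.25
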