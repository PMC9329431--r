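# shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

day_num <- function(d) as.integer(as.Date(d))

num_day <- function(n) as.Date(n, origin = "1970-01-01")

year_of <- function(d) as.integer(format(num_day(day_num(d)), "%Y"))

jan1 <- function(year) as.Date(sprintf("%d-01-01", year))

dec31 <- function(year) as.Date(sprintf("%d-12-31", year))

#' Day of year relative to a target year
#'
#' January 1 of `year` is day 1; days in the preceding year are zero or
#' negative, days in the following year run past 365/366.
#'
#' @param date a `Date` (or anything coercible).
#' @param year integer target year.
#' @return integer day-of-year.
#' @export
doy_rel <- function(date, year) day_num(date) - day_num(jan1(year)) + 1L

# half-away-from-zero rounding used for integer layer encoding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
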