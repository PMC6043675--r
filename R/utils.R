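#' @importFrom stats aggregate anova aov as.formula coef lm median model.matrix
#'   na.omit nls optim pf predict pt ptukey qnorm qt quantile resid rnorm runif
#'   rlnorm sd setNames var vcov integrate TukeyHSD residuals fitted terms
#'   contr.sum formula logLik
#' @importFrom utils head tail read.csv write.csv
#' @importFrom data.table data.table fread fwrite rbindlist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

HALF_HOUR_SECS <- 1800

#' Sequence of half-hourly timestamps
#'
#' Builds the regular 30-minute UTC grid spanning a date range, the sampling
#' grid used throughout the package (loggers store 30-min averages).
#'
#' @param from,to first and last calendar date (`Date` or coercible).
#' @return `POSIXct` vector, strictly increasing, 30-min spacing.
#' @export
halfHourlyGrid <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  stopifnot(to >= from)
  start <- as.POSIXct(paste(from, "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(to, "23:30:00"), tz = "UTC")
  seq(start, end, by = HALF_HOUR_SECS)
}

dateOf <- function(t) as.Date(t, tz = "UTC")

## fractional hour of day (0, 0.5, ..., 23.5)
hourOf <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

isHalfHourly <- function(t) {
  length(t) < 2L || all(diff(as.numeric(t)) == HALF_HOUR_SECS)
}

#' Month-window foliation test
#'
#' Phenology calendars here are month spans that may wrap the turn of the
#' year (e.g. December through June). Returns whether each date falls inside
#' the window; an all-year window (`1:12` span) is always `TRUE`.
#'
#' @param dates `Date` vector.
#' @param window integer length-2 `c(startMonth, endMonth)`, inclusive.
#' @return logical vector.
#' @export
inFoliationWindow <- function(dates, window) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- window[1]; e <- window[2]
  if (s <= e) m >= s & m <= e else m >= s | m <= e
}

## simple run-length starts/ends of a logical vector
logicalRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, value = r$values)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
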