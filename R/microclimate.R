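## Magnus saturation vapor pressure coefficients (hPa, dimensionless, degC).
## Configurable because dewpoint literature offers several coefficient sets.
MAGNUS <- c(es0 = 6.112, a = 17.62, b = 243.12)

#' Saturation vapor pressure (Magnus form)
#'
#' \eqn{e_s(T) = 6.112 \exp(17.62\, T / (243.12 + T))} hPa over water.
#'
#' @param temp air temperature, degC.
#' @param coef named Magnus coefficients `es0`, `a`, `b`.
#' @return saturation vapor pressure, hPa.
#' @export
saturationVapor <- function(temp, coef = MAGNUS) {
  unname(coef[["es0"]] * exp(coef[["a"]] * temp / (coef[["b"]] + temp)))
}

#' Vapor pressure deficit from temperature and relative humidity
#'
#' VPD = \eqn{e_s(T)\,(1 - RH/100)} in hPa, element-wise. VPD is the
#' atmospheric-demand driver of transpiration. Accepts plain numeric vectors
#' or a pair of aligned [HalfHourlySeries-class] objects (in which case a
#' VPD series is returned and out-of-range humidity errors name the
#' offending timestamp).
#'
#' @param temp air temperature (degC), numeric or a `"T"` series.
#' @param rh relative humidity (0--100 %), numeric or an `"RH"` series.
#' @param coef Magnus coefficients, see [saturationVapor()].
#' @return numeric VPD (hPa), or a `"VPD"` [HalfHourlySeries-class] when both
#'   inputs are series.
#' @examples
#' computeVPD(25, 50)  # half of e_s(25)
#' computeVPD(25, 100) # saturation: 0
#' @export
computeVPD <- function(temp, rh, coef = MAGNUS) {
  if (is(temp, "HalfHourlySeries") && is(rh, "HalfHourlySeries")) {
    stopifnot(identical(temp@time, rh@time))
    rhv <- rh@values
    bad <- which(!is.na(rhv) & (rhv < 0 | rhv > 100))
    if (length(bad)) {
      stop(sprintf(
        "RH outside [0, 100] at %s (value %.3g)",
        format(rh@time[bad[1]]), rhv[bad[1]]
      ))
    }
    vpd <- pmax(saturationVapor(temp@values, coef) * (1 - rhv / 100), 0)
    return(halfHourlySeries(temp@time, vpd, "VPD", site = temp@site))
  }
  if (any(!is.na(rh) & (rh < 0 | rh > 100)))
    stop("RH outside [0, 100]")
  pmax(saturationVapor(temp, coef) * (1 - rh / 100), 0)
}

#' Aggregate a half-hourly series to daily values
#'
#' Daily mean (and maximum) over the valid 30-min records of each calendar
#' day. Days with fewer than `minCoverage` x 48 valid records are flagged
#' invalid and their statistics set to `NA` rather than computed from a
#' partial day — a logger-failure day must not silently masquerade as a calm
#' day.
#'
#' @param series a [HalfHourlySeries-class] object.
#' @param minCoverage minimum fraction of the 48 daily records that must be
#'   valid; default 0.8 excludes logger-failure days while tolerating
#'   single gaps.
#' @param daytimeOnly restrict aggregation to 06:00--18:00 records (then
#'   coverage is judged against 24 records).
#' @return data.frame: `date`, `mean`, `max`, `nValid`, `valid`.
#' @export
dailyAggregate <- function(series, minCoverage = 0.8, daytimeOnly = FALSE) {
  stopifnot(is(series, "HalfHourlySeries"))
  tm <- series@time; v <- series@values
  if (!length(tm)) {
    return(data.frame(
      date = as.Date(character()), mean = numeric(), max = numeric(),
      nValid = integer(), valid = logical()
    ))
  }
  if (daytimeOnly) {
    keep <- hourOf(tm) >= 6 & hourOf(tm) < 18
    tm <- tm[keep]; v <- v[keep]
  }
  perDay <- if (daytimeOnly) 24L else 48L
  d <- dateOf(tm)
  dt <- data.table::data.table(date = d, v = v)
  out <- dt[, list(
    mean = mean(v, na.rm = TRUE),
    max = suppressWarnings(max(v, na.rm = TRUE)),
    nValid = sum(!is.na(v))
  ), by = "date"]
  out <- as.data.frame(out)
  out$valid <- out$nValid >= minCoverage * perDay
  out$mean[!out$valid] <- NA_real_
  out$max[!out$valid] <- NA_real_
  out$max[is.infinite(out$max)] <- NA_real_
  out[order(out$date), , drop = FALSE]
}

#' Build the daily driver table (SWC, VPD)
#'
#' Joins the daily aggregates of a soil-water-content series and a VPD
#' series into the driver table the statistical stages consume.
#'
#' @param swc `"SWC"` [HalfHourlySeries-class].
#' @param vpd `"VPD"` [HalfHourlySeries-class].
#' @param minCoverage see [dailyAggregate()].
#' @return data.frame: `date`, `swcMean`, `vpdMean`, `vpdMax`, `nValid`,
#'   `valid`.
#' @export
dailyDrivers <- function(swc, vpd, minCoverage = 0.8) {
  a <- dailyAggregate(swc, minCoverage)
  b <- dailyAggregate(vpd, minCoverage)
  out <- merge(
    data.frame(date = a$date, swcMean = a$mean, nSwc = a$nValid,
               validSwc = a$valid),
    data.frame(date = b$date, vpdMean = b$mean, vpdMax = b$max,
               nVpd = b$nValid, validVpd = b$valid),
    by = "date", all = TRUE
  )
  out$nValid <- pmin(out$nSwc, out$nVpd, na.rm = FALSE)
  out$valid <- !is.na(out$validSwc) & !is.na(out$validVpd) &
    out$validSwc & out$validVpd
  out[, c("date", "swcMean", "vpdMean", "vpdMax", "nValid", "valid")]
}

#' Classify two-week dry and wet soil-moisture periods
#'
#' Scans the daily SWC series for maximal contiguous runs of at least
#' `windowDays` days entirely below the dry threshold (default 15 %) or
#' entirely above the wet threshold (default 25 %). Each qualifying run is
#' reported as one period trimmed to exactly `windowDays` days from its
#' start, the convention used for the dry/wet contrasts. Days inside no
#' qualifying window are `"neither"`.
#'
#' @param daily driver table from [dailyDrivers()] (needs `date`, `swcMean`).
#' @param dryThresh,wetThresh SWC thresholds, %.
#' @param windowDays period length, days.
#' @return data.frame: `label` (`"dry"`/`"wet"`), `start`, `end` (trimmed,
#'   `end = start + windowDays - 1`), `runEnd` (end of the full qualifying
#'   run). Zero rows (with a warning) when the series is shorter than the
#'   window.
#' @export
classifyMoisturePeriods <- function(daily, dryThresh = 15, wetThresh = 25,
                                    windowDays = 14) {
  empty <- data.frame(
    label = character(), start = as.Date(character()),
    end = as.Date(character()), runEnd = as.Date(character())
  )
  daily <- daily[order(daily$date), , drop = FALSE]
  if (nrow(daily) < windowDays) {
    warning("series shorter than the classification window")
    return(empty)
  }
  onePass <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    runs <- logicalRuns(cond)
    runs <- runs[runs$value & (runs$end - runs$start + 1L) >= windowDays, ,
                 drop = FALSE]
    if (!nrow(runs)) return(empty)
    data.frame(
      label = label,
      start = daily$date[runs$start],
      end = daily$date[runs$start] + windowDays - 1L,
      runEnd = daily$date[runs$end]
    )
  }
  out <- rbind(
    onePass(daily$swcMean < dryThresh, "dry"),
    onePass(daily$swcMean > wetThresh, "wet")
  )
  out[order(out$start), , drop = FALSE]
}

#' Label each day with its moisture period
#'
#' @param dates `Date` vector to label.
#' @param periods period table from [classifyMoisturePeriods()].
#' @return character vector `"dry"`/`"wet"`/`"neither"`.
#' @export
moistureLabel <- function(dates, periods) {
  lab <- rep("neither", length(dates))
  if (nrow(periods)) {
    for (i in seq_len(nrow(periods))) {
      hit <- dates >= periods$start[i] & dates <= periods$end[i]
      lab[hit] <- periods$label[i]
    }
  }
  lab
}
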