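## Granier calibration: u = 119e-6 K^1.231 m3 m-2 s-1. Converted to mass
## flux per sapwood area: 119e-6 m/s x 100 cm/m x 3600 s/h = 42.84 cm/h,
## times an assumed sap density of 1 g cm-3 -> 42.84 g cm-2 h-1.
GRANIER_A <- 42.84
GRANIER_B <- 1.231

#' Estimate the zero-flow temperature differential baseline
#'
#' The TDP method needs the temperature differential at zero sap flow,
#' \eqn{\Delta T_{max}}. It is taken as the maximum predawn (00:00--06:00)
#' differential within a centred moving window of `windowDays` days, giving
#' a piecewise-constant daily baseline that tracks slow sensor drift while
#' being robust to single nights with non-zero nocturnal flow.
#'
#' Sensor noise would otherwise inflate a running maximum by ~2.5 SD (the
#' max over ~120 half-hourly records), so the differential is smoothed with
#' a short centred running mean before the maxima are taken; under zero
#' flow the smoothed value still equals \eqn{\Delta T_{max}} exactly.
#'
#' @param signal a `"dT"` [HalfHourlySeries-class] (one tree, one azimuth).
#' @param windowDays moving-window length in days (default 10).
#' @param predawnHours numeric length-2, the nocturnal window (hour-of-day,
#'   records with `predawnHours[1] <= h < predawnHours[2]` are used).
#' @param smoothRecords width (records) of the centred running mean applied
#'   before maxima are taken; 1 disables smoothing.
#' @return data.frame: `date`, `dTmax` (`NA` where no nocturnal data fall in
#'   the window).
#' @export
estimateDeltaTmax <- function(signal, windowDays = 10,
                              predawnHours = c(0, 6), smoothRecords = 5) {
  stopifnot(is(signal, "HalfHourlySeries"), signal@channel == "dT")
  tm <- signal@time; v <- signal@values
  if (smoothRecords > 1 && length(v) >= smoothRecords) {
    sm <- stats::filter(v, rep(1 / smoothRecords, smoothRecords),
                        sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  h <- hourOf(tm)
  night <- h >= predawnHours[1] & h < predawnHours[2]
  d <- dateOf(tm)
  days <- seq(min(d), max(d), by = "day")
  nm <- tapply(v[night], factor(as.character(d[night]),
                                levels = as.character(days)),
               function(x) if (all(is.na(x))) NA_real_
                           else max(x, na.rm = TRUE))
  nightMax <- as.numeric(nm)
  half <- (windowDays - 1) / 2
  base <- vapply(seq_along(days), function(i) {
    lo <- days[i] - ceiling(half); hi <- days[i] + floor(half)
    x <- nightMax[days >= lo & days <= hi]
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }, numeric(1))
  data.frame(date = days, dTmax = base)
}

#' Granier flow index
#'
#' \eqn{K = (\Delta T_{max} - \Delta T)/\Delta T}. Negative values (nocturnal
#' anomalies where the differential exceeds the baseline) are clipped to
#' zero; the number of clipped records is attached as attribute
#' `"nClipped"`.
#'
#' @param dT temperature differential, K (must be > 0 where valid).
#' @param dTmax zero-flow baseline, K (recycled; must be > 0).
#' @return numeric K >= 0, with attribute `nClipped`.
#' @export
computeK <- function(dT, dTmax) {
  if (any(!is.na(dT) & dT <= 0)) stop("dT must be > 0 wherever valid")
  if (any(!is.na(dTmax) & dTmax <= 0)) stop("dTmax must be > 0")
  k <- (dTmax - dT) / dT
  nClip <- sum(!is.na(k) & k < 0)
  k[!is.na(k) & k < 0] <- 0
  attr(k, "nClipped") <- nClip
  k
}

#' Sap flux density from the flow index
#'
#' Granier's empirical calibration \eqn{J_s = a K^b} with
#' \eqn{a = 42.84} g cm-2 h-1 (the original 119e-6 m3 m-2 s-1 expressed as
#' mass flux assuming sap density 1 g cm-3) and \eqn{b = 1.231}.
#'
#' @param K flow index, >= 0 (negative input is an error: clipping belongs
#'   upstream in [computeK()]).
#' @param a,b calibration coefficients.
#' @return sap flux density Js, g cm-2 h-1.
#' @export
kToFlux <- function(K, a = GRANIER_A, b = GRANIER_B) {
  if (any(!is.na(K) & K < 0)) stop("K must be >= 0 (clip upstream)")
  a * K^b
}

#' Full TDP conversion for one sensor
#'
#' Convenience wrapper: baseline estimation, flow index and calibration in
#' one step, returning a `"Js"` series aligned with the input.
#'
#' @param signal `"dT"` [HalfHourlySeries-class].
#' @param baseline optional baseline table (`date`, `dTmax`) to use instead
#'   of estimating one (e.g. a known seasonal constant); default `NULL`
#'   estimates via [estimateDeltaTmax()].
#' @param windowDays,predawnHours,smoothRecords passed to
#'   [estimateDeltaTmax()].
#' @param a,b passed to [kToFlux()].
#' @return `"Js"` [HalfHourlySeries-class]; attributes `nClipped` and
#'   `baseline` (the baseline table used).
#' @export
sensorFlux <- function(signal, baseline = NULL, windowDays = 10,
                       predawnHours = c(0, 6), smoothRecords = 5,
                       a = GRANIER_A, b = GRANIER_B) {
  if (is.null(baseline))
    baseline <- estimateDeltaTmax(signal, windowDays, predawnHours,
                                  smoothRecords)
  d <- dateOf(signal@time)
  dTmax <- baseline$dTmax[match(d, baseline$date)]
  k <- computeK(signal@values, dTmax)
  js <- kToFlux(as.numeric(k), a = a, b = b)
  out <- halfHourlySeries(signal@time, js, "Js", site = signal@site,
                          tree = signal@tree)
  attr(out, "nClipped") <- attr(k, "nClipped")
  attr(out, "baseline") <- baseline
  out
}

#' Average the two azimuth sensors of a tree
#'
#' Each tree carries a north- and a south-facing sensor; the tree-level flux
#' is their arithmetic mean per timestamp. Where one azimuth is missing the
#' other is used alone (count reported via attribute `nSingle`); both
#' missing stays missing.
#'
#' @param north,south `"Js"` [HalfHourlySeries-class] on identical grids.
#' @return combined `"Js"` series with attribute `nSingle`.
#' @export
combineAzimuths <- function(north, south) {
  stopifnot(identical(north@time, south@time))
  m <- cbind(north@values, south@values)
  js <- rowMeans(m, na.rm = TRUE)
  js[is.nan(js)] <- NA_real_
  nSingle <- sum(rowSums(is.na(m)) == 1L)
  out <- halfHourlySeries(north@time, js, "Js", site = north@site,
                          tree = north@tree)
  attr(out, "nSingle") <- nSingle
  out
}

#' Daily per-tree flux summaries
#'
#' Per calendar day: the daily sum of sap flux density (each 30-min record
#' contributes value x 0.5 h, giving g cm-2 day-1), the daily mean and the
#' daily maximum of the half-hourly values, plus the foliation flag from the
#' tree's phenology window. Days below the coverage threshold are flagged
#' invalid with `NA` statistics.
#'
#' @param flux `"Js"` [HalfHourlySeries-class] for one tree.
#' @param foliationWindow integer `c(startMonth, endMonth)` or `NULL`
#'   (always foliated), see [inFoliationWindow()].
#' @param minCoverage minimum fraction of the 48 records required.
#' @return data.frame: `tree`, `date`, `jsSum`, `jsMean`, `jsMax`, `nValid`,
#'   `valid`, `foliated`.
#' @export
summarizeDaily <- function(flux, foliationWindow = NULL, minCoverage = 0.8) {
  stopifnot(is(flux, "HalfHourlySeries"), flux@channel == "Js")
  agg <- dailyAggregate(flux, minCoverage)
  d <- dateOf(flux@time)
  dt <- data.table::data.table(date = d, v = flux@values)
  sums <- as.data.frame(dt[, list(jsSum = sum(v, na.rm = TRUE) * 0.5),
                           by = "date"])
  out <- merge(agg, sums, by = "date")
  out$jsSum[!out$valid] <- NA_real_
  data.frame(
    tree = flux@tree %||% NA_character_,
    date = out$date,
    jsSum = out$jsSum, jsMean = out$mean, jsMax = out$max,
    nValid = out$nValid, valid = out$valid,
    foliated = if (is.null(foliationWindow)) TRUE
               else inFoliationWindow(out$date, foliationWindow)
  )
}
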