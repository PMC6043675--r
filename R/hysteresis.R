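#' Signed shoelace area of a closed polygon
#'
#' \eqn{\tfrac12 \sum_i (x_i y_{i+1} - x_{i+1} y_i)} with the last vertex
#' closed back to the first. Counterclockwise traversal gives a positive
#' sign; in the (x = VPD, y = Js) plane a clockwise loop (negative area)
#' means sap flux peaks before atmospheric demand.
#'
#' @param x,y vertex coordinates in traversal order (not pre-closed).
#' @return signed area; attribute `selfIntersecting` flags edge crossings
#'   (the magnitude is still reported).
#' @export
shoelaceArea <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  n <- length(x)
  a <- 0.5 * sum(xs[1:n] * ys[2:(n + 1)] - xs[2:(n + 1)] * ys[1:n])
  attr(a, "selfIntersecting") <- polygonSelfIntersects(x, y)
  a
}

## segment-crossing test over all non-adjacent edge pairs; O(n^2), n <= 48
polygonSelfIntersects <- function(x, y) {
  n <- length(x)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  segInt <- function(i, j) {
    d1 <- cross(xs[j], ys[j], xs[j + 1], ys[j + 1], xs[i], ys[i])
    d2 <- cross(xs[j], ys[j], xs[j + 1], ys[j + 1], xs[i + 1], ys[i + 1])
    d3 <- cross(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[j], ys[j])
    d4 <- cross(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[j + 1], ys[j + 1])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segInt(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Build one day's diurnal hysteresis loop
#'
#' Averages the half-hourly group flux and VPD to hourly vertices
#' (00:00 ... 23:00), closes the polygon, and computes the shoelace area,
#' rotation direction and peak times. Loops with more than 20 % of the
#' hours missing are rejected. With `resolution = "halfhour"` the 48
#' half-hourly vertices are used instead, allowing half-hour peak times.
#'
#' @param flux `"Js"` [HalfHourlySeries-class] (typically the mean over a
#'   species x elevation group's trees, see [averageSeries()]).
#' @param vpd `"VPD"` [HalfHourlySeries-class] on the same grid.
#' @param date the day to extract.
#' @param group label carried into the result.
#' @param resolution `"hourly"` (default, matching the loop construction
#'   from simultaneous hourly averages) or `"halfhour"`.
#' @return a [HysteresisLoop-class] object.
#' @export
buildLoop <- function(flux, vpd, date, group = "all",
                      resolution = c("hourly", "halfhour")) {
  resolution <- match.arg(resolution)
  stopifnot(identical(flux@time, vpd@time))
  date <- as.Date(date)
  sel <- dateOf(flux@time) == date
  if (!any(sel)) stop("date not covered by the series")
  h <- hourOf(flux@time[sel])
  js <- flux@values[sel]; vp <- vpd@values[sel]
  if (resolution == "hourly") {
    bin <- floor(h)
    js <- tapply(js, bin, mean, na.rm = TRUE)
    vp <- tapply(vp, bin, mean, na.rm = TRUE)
    hh <- as.numeric(names(js))
  } else {
    hh <- h
  }
  ok <- is.finite(js) & is.finite(vp)
  nExp <- if (resolution == "hourly") 24L else 48L
  if (sum(ok) < 0.8 * nExp)
    stop(sprintf("loop rejected: %d/%d vertices missing", nExp - sum(ok), nExp))
  hh <- hh[ok]; js <- as.numeric(js[ok]); vp <- as.numeric(vp[ok])
  a <- shoelaceArea(vp, js)
  degen <- abs(a) < 1e-9 * max(1, diff(range(vp)) * diff(range(js)))
  rot <- if (degen) "degenerate" else if (a < 0) "clockwise" else "counterclockwise"
  new("HysteresisLoop",
    date = date, group = group, hour = hh, vpd = vp, js = js,
    signedArea = as.numeric(a), rotation = rot,
    jsPeak = hh[which.max(js)], vpdPeak = hh[which.max(vp)],
    selfIntersecting = attr(a, "selfIntersecting")
  )
}

#' Average several aligned series
#'
#' Per-timestamp mean over trees of a group (e.g. the four trees of one
#' species at one elevation), ignoring missing records.
#'
#' @param seriesList list of aligned [HalfHourlySeries-class] objects.
#' @return a [HalfHourlySeries-class] of the same channel.
#' @export
averageSeries <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  tm <- seriesList[[1]]@time
  for (s in seriesList) stopifnot(identical(s@time, tm))
  m <- vapply(seriesList, seriesValues, numeric(length(tm)))
  v <- rowMeans(as.matrix(m), na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  halfHourlySeries(tm, v, seriesList[[1]]@channel,
                   site = seriesList[[1]]@site)
}

#' Contrast wet-day and dry-day hysteresis loops
#'
#' For every group present in both lists, reports the loop-area ratio
#' |area|dry / |area|wet, both rotation directions, and the sap-flux
#' peak-time shift (dry minus wet, hours). Groups missing one condition are
#' omitted.
#'
#' @param wetLoops,dryLoops lists of [HysteresisLoop-class] objects.
#' @return data.frame: `group`, `areaWet`, `areaDry`, `areaRatio`,
#'   `rotationWet`, `rotationDry`, `jsPeakShift`.
#' @export
compareWetDryLoops <- function(wetLoops, dryLoops) {
  gw <- vapply(wetLoops, function(l) l@group, character(1))
  gd <- vapply(dryLoops, function(l) l@group, character(1))
  groups <- intersect(gw, gd)
  do.call(rbind, lapply(groups, function(g) {
    w <- wetLoops[[match(g, gw)]]; d <- dryLoops[[match(g, gd)]]
    data.frame(
      group = g,
      areaWet = abs(w@signedArea), areaDry = abs(d@signedArea),
      areaRatio = abs(d@signedArea) / abs(w@signedArea),
      rotationWet = w@rotation, rotationDry = d@rotation,
      jsPeakShift = d@jsPeak - w@jsPeak
    )
  }))
}
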