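# shared fixture builders (all data generated in code)

constantSeries <- function(value, channel, from = "2015-01-01",
                           to = "2015-01-01", site = NULL, tree = NULL) {
  tm <- halfHourlyGrid(from, to)
  halfHourlySeries(tm, rep(value, length(tm)), channel,
                   site = site, tree = tree)
}

# daily driver table with a given SWC trace (one value per day)
driversFromSwc <- function(swc, start = "2015-01-01", vpdMean = 8,
                           vpdMax = 15) {
  data.frame(
    date = as.Date(start) + seq_along(swc) - 1,
    swcMean = swc, vpdMean = vpdMean, vpdMax = vpdMax,
    nValid = 48L, valid = TRUE
  )
}

# independent Magnus oracle, written out directly
esatOracle <- function(t) 6.112 * exp(17.62 * t / (243.12 + t))

# brute-force scan over all possible 14-day windows (oracle for the
# period classifier): returns logical per day "inside some qualifying
# maximal run"
scanWindowsOracle <- function(x, thresh, window = 14, above = FALSE) {
  n <- length(x)
  hit <- rep(FALSE, n)
  for (s in seq_len(n - window + 1)) {
    w <- x[s:(s + window - 1)]
    ok <- if (above) all(w > thresh) else all(w < thresh)
    if (ok) hit[s:(s + window - 1)] <- TRUE
  }
  hit
}
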