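test_that("flow index follows Granier's ratio with clip accounting", {
  expect_equal(as.numeric(computeK(10, 10)), 0)
  expect_equal(as.numeric(computeK(8, 10)), 0.25)
  k <- computeK(10.5, 10)
  expect_equal(as.numeric(k), 0)
  expect_equal(attr(k, "nClipped"), 1L)
  expect_error(computeK(-1, 10), "dT")
  expect_error(computeK(c(5, 0), 10), "dT")
})

test_that("calibration constant matches the original unit conversion", {
  # 119e-6 m3 m-2 s-1 -> cm3 cm-2 h-1: x 100 (m->cm) x 3600 (s->h)
  expect_equal(119e-6 * 100 * 3600, 42.84)
  expect_equal(kToFlux(0), 0)
  expect_equal(kToFlux(1), 42.84)
  # independent power evaluation
  expect_equal(kToFlux(0.25), 42.84 * exp(1.231 * log(0.25)), tolerance = 1e-12)
  expect_error(kToFlux(-0.1), "K")
  # strictly increasing
  k <- seq(0, 2, by = 0.01)
  expect_true(all(diff(kToFlux(k)) > 0))
})

test_that("baseline estimation recovers constant and drifting nocturnal maxima", {
  tm <- halfHourlyGrid("2015-03-01", "2015-03-10")
  h <- as.POSIXlt(tm, tz = "UTC")$hour
  # constant nocturnal dT = 10 K, daytime depression to 7
  v <- ifelse(h >= 7 & h < 19, 7, 10)
  s <- halfHourlySeries(tm, v, "dT", tree = "t1")
  b <- estimateDeltaTmax(s, windowDays = 10)
  expect_equal(b$dTmax, rep(10, 10))

  # linear nocturnal drift, window of one day tracks each night's max
  drift <- 10 + 2 * (as.numeric(tm) - as.numeric(tm[1])) /
    (as.numeric(tm[length(tm)]) - as.numeric(tm[1]))
  v2 <- ifelse(h >= 7 & h < 19, 5, drift)
  b2 <- estimateDeltaTmax(halfHourlySeries(tm, v2, "dT"), windowDays = 1)
  nightly <- tapply(drift[h < 6], as.Date(tm, tz = "UTC")[h < 6], max)
  expect_equal(b2$dTmax, as.numeric(nightly))
})

test_that("baseline recovered within 1% from a noisy synthetic signal", {
  # known dTmax = 9.5 K with daytime depression and small sensor noise
  tm <- halfHourlyGrid("2015-03-01", "2015-03-12")
  h <- hourOf(tm)
  depress <- 3 * pmax(0, sin(pi * (h - 6) / 12))
  set.seed(7)
  v <- 9.5 - depress + rnorm(length(tm), 0, 0.02)
  b <- estimateDeltaTmax(halfHourlySeries(tm, pmax(v, 0.1), "dT"))
  expect_true(all(abs(b$dTmax - 9.5) / 9.5 < 0.01))
})

test_that("azimuth combination averages with single-sensor fallback", {
  n <- constantSeries(4, "Js", tree = "t1")
  s <- constantSeries(6, "Js", tree = "t1")
  expect_equal(seriesValues(combineAzimuths(n, s)), rep(5, 48))
  # one azimuth missing at a timestamp: use the other, count it
  sv <- seriesValues(s); sv[5] <- NA
  s2 <- halfHourlySeries(seriesTimes(s), sv, "Js", tree = "t1")
  comb <- combineAzimuths(n, s2)
  expect_equal(seriesValues(comb)[5], 4)
  expect_equal(attr(comb, "nSingle"), 1L)
  # identity
  expect_equal(seriesValues(combineAzimuths(n, n)), seriesValues(n))
})

test_that("daily summaries integrate flux and flag foliation", {
  f <- constantSeries(10, "Js", tree = "t1")
  d <- summarizeDaily(f)
  expect_equal(d$jsSum, 240)  # 48 records x 10 x 0.5 h
  expect_equal(d$jsMean, 10)
  expect_equal(d$jsMax, 10)

  # half-sine day: max lands on the solar-noon record
  tm <- halfHourlyGrid("2015-03-01", "2015-03-01")
  h <- hourOf(tm)
  js <- 12 * pmax(0, sin(pi * (h - 6) / 12))
  d2 <- summarizeDaily(halfHourlySeries(tm, js, "Js", tree = "t1"))
  expect_equal(d2$jsMax, 12)

  # December-June foliation window wraps the year boundary
  tmS <- halfHourlyGrid("2015-05-28", "2015-07-03")
  fS <- halfHourlySeries(tmS, rep(1, length(tmS)), "Js", tree = "t1")
  dS <- summarizeDaily(fS, foliationWindow = c(12L, 6L))
  expect_true(all(dS$foliated[format(dS$date, "%m") == "06"]))
  expect_false(any(dS$foliated[format(dS$date, "%m") == "07"]))
})

test_that("TDP round trip is exact with a supplied baseline", {
  cfg <- studyConfig(to = "2015-01-20")
  clim <- genMicroclimate(860, cfg$dates$from, cfg$dates$to, seed = 11,
                          config = cfg$microclimate)
  clim$VPD <- computeVPD(clim$T, clim$RH)
  js <- genTrueFlux(cfg$species$Ceiba, clim, seed = 12, noiseSdLog = 0)
  sig <- invertToSensorSignals(js, 9.8, 9.8, noiseSd = 0, seed = 13,
                               azimuthOffset = 0)
  s <- halfHourlySeries(clim$time, sig$north, "dT", tree = "t1")
  supplied <- data.frame(date = unique(as.Date(clim$time, tz = "UTC")),
                         dTmax = 9.8)
  rec <- sensorFlux(s, baseline = supplied)
  expect_equal(seriesValues(rec), js, tolerance = 1e-9)
})
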