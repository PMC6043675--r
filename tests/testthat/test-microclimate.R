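test_that("VPD follows the Magnus form with sane limits", {
  # saturation => zero deficit; dry air at 0 degC => es(0) = 6.112
  expect_equal(computeVPD(25, 100), 0)
  expect_equal(computeVPD(0, 0), 6.112)
  # half humidity gives half of saturation pressure (independent oracle)
  expect_equal(computeVPD(25, 50), esatOracle(25) / 2, tolerance = 1e-12)
  expect_error(computeVPD(20, 120), "RH")
})

test_that("VPD is monotone in both drivers over a grid", {
  tgrid <- seq(-5, 40, by = 2.5)
  rhgrid <- seq(0, 100, by = 5)
  for (tt in tgrid) {
    v <- computeVPD(rep(tt, length(rhgrid)), rhgrid)
    expect_true(all(diff(v) <= 0))  # decreasing in RH
  }
  for (rh in setdiff(rhgrid, 100)) {
    v <- computeVPD(tgrid, rep(rh, length(tgrid)))
    expect_true(all(diff(v) > 0))  # increasing in T
  }
})

test_that("series-level VPD names the offending timestamp", {
  tm <- halfHourlyGrid("2015-02-03", "2015-02-03")
  tser <- halfHourlySeries(tm, rep(20, 48), "T")
  rhv <- rep(80, 48)
  rh <- halfHourlySeries(tm, rhv, "RH")
  rh@values[10] <- 105  # bypass constructor validity to hit the op check
  expect_error(computeVPD(tser, rh), "2015-02-03 04:30")
  out <- computeVPD(tser, halfHourlySeries(tm, rhv, "RH"))
  expect_s4_class(out, "HalfHourlySeries")
  expect_true(all(seriesValues(out) >= 0))
})

test_that("daily aggregation handles constants, gaps and coverage", {
  s <- constantSeries(20, "SWC")
  agg <- dailyAggregate(s)
  expect_equal(agg$mean, 20)
  expect_equal(agg$nValid, 48L)

  # 10 valid records out of 48 at min coverage 0.5 -> flagged missing
  v <- rep(NA_real_, 48); v[1:10] <- 20
  s2 <- halfHourlySeries(halfHourlyGrid("2015-01-01", "2015-01-01"), v, "SWC")
  agg2 <- dailyAggregate(s2, minCoverage = 0.5)
  expect_false(agg2$valid)
  expect_true(is.na(agg2$mean))

  # alternating VPD 0/10: mean 5, max 10
  s3 <- halfHourlySeries(halfHourlyGrid("2015-01-01", "2015-01-01"),
                         rep(c(0, 10), 24), "VPD")
  agg3 <- dailyAggregate(s3)
  expect_equal(agg3$mean, 5)
  expect_equal(agg3$max, 10)

  # empty series -> empty result, not an error
  s0 <- halfHourlySeries(as.POSIXct(character(), tz = "UTC"), numeric(), "SWC")
  expect_equal(nrow(dailyAggregate(s0)), 0L)
})

test_that("constant series mean is coverage-pattern invariant", {
  set.seed(42)
  for (i in 1:10) {
    v <- rep(7.5, 48)
    v[sample(48, sample(0:8, 1))] <- NA  # up to 8 gaps, still above 0.8
    s <- halfHourlySeries(halfHourlyGrid("2015-01-01", "2015-01-01"), v, "SWC")
    expect_equal(dailyAggregate(s)$mean, 7.5)
  }
})

test_that("moisture periods find maximal runs and trim to two weeks", {
  # 20 consecutive dry days -> one dry period covering the first 14
  d <- driversFromSwc(rep(10, 20))
  p <- classifyMoisturePeriods(d)
  expect_equal(nrow(p), 1L)
  expect_equal(p$label, "dry")
  expect_equal(as.integer(p$end - p$start) + 1L, 14L)
  expect_equal(p$start, d$date[1])

  # 13 dry days then wet: window unmet
  p2 <- classifyMoisturePeriods(driversFromSwc(c(rep(10, 13), rep(30, 5))))
  expect_false(any(p2$label == "dry"))

  # wet fortnight then dry fortnight: one of each, matching a brute-force
  # window scan
  x <- c(rep(30, 14), rep(10, 14))
  p3 <- classifyMoisturePeriods(driversFromSwc(x))
  expect_setequal(p3$label, c("wet", "dry"))
  oracleDry <- scanWindowsOracle(x, 15, above = FALSE)
  oracleWet <- scanWindowsOracle(x, 25, above = TRUE)
  lab <- moistureLabel(driversFromSwc(x)$date, p3)
  expect_true(all(lab[oracleDry] == "dry"))
  expect_true(all(lab[oracleWet] == "wet"))

  # shorter than the window: empty with a warning
  expect_warning(p4 <- classifyMoisturePeriods(driversFromSwc(rep(10, 5))),
                 "shorter")
  expect_equal(nrow(p4), 0L)
})

test_that("period classification ignores prepended neutral days", {
  x <- c(rep(10, 16), rep(20, 10))
  base <- classifyMoisturePeriods(driversFromSwc(x, start = "2015-02-01"))
  padded <- classifyMoisturePeriods(
    driversFromSwc(c(rep(20, 7), x), start = "2015-01-25"))
  expect_equal(base$label, padded$label)
  expect_equal(base$start, padded$start)
  expect_equal(base$end, padded$end)
})
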