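smallConfig <- function(days = 30, trees = 1L) {
  studyConfig(to = format(as.Date("2015-01-01") + days - 1),
              treesPerSpecies = trees)
}

test_that("microclimate generation is deterministic and physically bounded", {
  cfg <- studyConfig()$microclimate
  a <- genMicroclimate(860, "2015-01-01", "2015-02-15", seed = 5, config = cfg)
  b <- genMicroclimate(860, "2015-01-01", "2015-02-15", seed = 5, config = cfg)
  expect_identical(a, b)
  expect_true(all(a$RH <= 100 & a$RH >= 0))
  expect_true(all(a$SWC >= 0 & a$SWC <= 100))
  expect_true(all(computeVPD(a$T, a$RH) >= 0))
})

test_that("March soil moisture is ordered along the elevation gradient", {
  cfg <- studyConfig()$microclimate
  ordered <- vapply(1:100, function(s) {
    m <- vapply(c(670, 860, 1100), function(el) {
      cl <- genMicroclimate(el, "2015-03-01", "2015-03-31", seed = s,
                            config = cfg)
      mean(cl$SWC)
    }, numeric(1))
    m[1] < m[2] && m[2] < m[3]
  }, logical(1))
  expect_gte(mean(ordered), 0.95)
})

test_that("true flux respects the demand threshold and phenology", {
  cfg <- smallConfig(40)
  clim <- genMicroclimate(860, cfg$dates$from, cfg$dates$to, seed = 2,
                          config = cfg$microclimate)
  clim$VPD <- computeVPD(clim$T, clim$RH)

  # no atmospheric demand -> no flux at all
  clim0 <- clim; clim0$VPD <- rep(0, nrow(clim0))
  js0 <- genTrueFlux(cfg$species$Ceiba, clim0, seed = 3)
  expect_true(all(js0 == 0))

  # defoliated days stay below 2% of the base flux
  sp <- cfg$species$Eriotheca
  climJul <- genMicroclimate(860, "2015-07-01", "2015-07-20", seed = 2,
                             config = cfg$microclimate)
  climJul$VPD <- computeVPD(climJul$T, climJul$RH)
  jsJul <- genTrueFlux(sp, climJul, seed = 3)
  expect_true(all(jsJul < 0.02 * sp$S * 2))  # x2 headroom for lognormal noise
  expect_lt(quantile(jsJul, 0.99), 0.02 * sp$S)
})

test_that("the evergreen keeps dry-period flux at or above wet-period flux", {
  cfg <- studyConfig()
  ok <- vapply(1:20, function(s) {
    clim <- genMicroclimate(860, "2015-01-01", "2015-04-30", seed = s,
                            config = cfg$microclimate)
    clim$VPD <- computeVPD(clim$T, clim$RH)
    js <- genTrueFlux(cfg$species$Capparis, clim, seed = s + 1000)
    day <- as.Date(clim$time, tz = "UTC")
    dm <- tapply(js, day, mean)
    swc <- tapply(clim$SWC, day, mean)
    mean(dm[swc < 15]) >= mean(dm[swc > 25])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("sensor inversion honours the zero-flux baseline and round-trips", {
  sig <- invertToSensorSignals(rep(0, 10), 9.5, 10.5, noiseSd = 0, seed = 1,
                               azimuthOffset = 0)
  expect_equal(sig$north, rep(9.5, 10))
  expect_equal(sig$south, rep(10.5, 10))

  # zero-noise pipeline round trip through baseline estimation: < 0.5% RMS
  cfg <- smallConfig(25)
  clim <- genMicroclimate(670, cfg$dates$from, cfg$dates$to, seed = 9,
                          config = cfg$microclimate)
  clim$VPD <- computeVPD(clim$T, clim$RH)
  js <- genTrueFlux(cfg$species$Erythrina, clim, seed = 10, noiseSdLog = 0)
  sig <- invertToSensorSignals(js, 10, 10, noiseSd = 0, seed = 11,
                               azimuthOffset = 0.03)
  rec <- combineAzimuths(
    sensorFlux(halfHourlySeries(clim$time, sig$north, "dT", tree = "t")),
    sensorFlux(halfHourlySeries(clim$time, sig$south, "dT", tree = "t"))
  )
  rms <- sqrt(mean((seriesValues(rec) - js)^2)) / sqrt(mean(js^2))
  expect_lt(rms, 0.005)
})

test_that("0.05 K sensor noise leaves daily maxima within 5% (median)", {
  # wet-season window: the regime whose maxima the analyses compare
  cfg <- studyConfig(from = "2015-03-15", to = "2015-04-15")
  clim <- genMicroclimate(860, cfg$dates$from, cfg$dates$to, seed = 71,
                          config = cfg$microclimate)
  clim$VPD <- computeVPD(clim$T, clim$RH)
  js <- genTrueFlux(cfg$species$Ceiba, clim, seed = 72, noiseSdLog = 0)
  day <- as.Date(clim$time, tz = "UTC")
  trueMax <- tapply(js, day, max)
  err <- vapply(1:50, function(s) {
    sig <- invertToSensorSignals(js, 10, 10, noiseSd = 0.05, seed = s)
    rec <- combineAzimuths(
      sensorFlux(halfHourlySeries(clim$time, sig$north, "dT", tree = "t")),
      sensorFlux(halfHourlySeries(clim$time, sig$south, "dT", tree = "t"))
    )
    recMax <- tapply(seriesValues(rec), day, max)
    median(abs(recMax - trueMax) / trueMax)
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("radial observations reflect each species' true shape", {
  cfg <- studyConfig()
  depths <- seq(0.5, 7.5, 1)
  # zero noise reproduces the Gaussian exactly (up to the flux scale)
  obs <- genRadialObservations(cfg$species$Ceiba, noiseSd = 0, seed = 1,
                               fluxScale = 5)
  tr <- cfg$species$Ceiba
  f <- exp(-(depths - tr$profileMu)^2 / (2 * tr$profileSigma^2))
  expect_equal(obs$value / max(obs$value), f / max(f), tolerance = 1e-12)
  # hump-shaped: maximum between 1 and 3 cm beneath the cambium
  expect_true(obs$depth[which.max(obs$value)] >= 1 &&
              obs$depth[which.max(obs$value)] <= 3)
  # outer-xylem maximum for the species peaking at the bark
  obsE <- genRadialObservations(cfg$species$Eriotheca, noiseSd = 0, seed = 1)
  expect_equal(which.max(obsE$value), 1L)
  # the evergreen has no HFD truth: generation must refuse
  expect_error(genRadialObservations(cfg$species$Capparis, seed = 1), "HFD")
})

test_that("the default study design has 44 trees and no evergreen on top", {
  st <- simulateStudy(smallConfig(3, trees = 4L), seed = 2)
  tr <- studyTrees(st)
  expect_equal(nrow(tr), 44L)
  expect_equal(sum(tr$species == "Capparis" & tr$elevation == 1100), 0L)
  expect_equal(as.vector(table(tr$species)[c("Ceiba", "Eriotheca", "Erythrina")]),
               rep(12L, 3))
  expect_true(all(tr$dbh > 15))
})

test_that("generated DBH tracks the design's cell means", {
  # pooled over seeds, cell means must sit within 2 SE of the configured ones
  cfg <- smallConfig(2)
  dbh <- do.call(rbind, lapply(1:12, function(s)
    studyTrees(simulateStudy(cfg, seed = s))[, c("species", "elevation", "dbh")]))
  for (sp in c("Ceiba", "Capparis")) {
    for (el in if (sp == "Capparis") c(670, 860) else c(670, 860, 1100)) {
      pars <- sapflux::studyConfig()$trees$dbh[[sp]][[as.character(el)]]
      x <- dbh$dbh[dbh$species == sp & dbh$elevation == el]
      expect_lt(abs(mean(x) - pars[1]), 2 * pars[2] / sqrt(length(x)) + 1e-9)
    }
  }
})

test_that("fixture writing is deterministic and refuses to clobber", {
  cfg <- smallConfig(5)
  st <- simulateStudy(cfg, seed = 7)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  m1 <- writeFixtureDataset(st, d1)
  m2 <- writeFixtureDataset(simulateStudy(cfg, seed = 7), d2)
  expect_equal(m1$md5, m2$md5)
  expect_error(writeFixtureDataset(st, d1), "force")
  m3 <- writeFixtureDataset(simulateStudy(cfg, seed = 8), d1, force = TRUE)
  expect_false(all(m3$md5 == m1$md5))
  unlink(c(d1, d2), recursive = TRUE)
})
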