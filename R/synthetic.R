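## Deterministic sub-seed derivation (kept below 2^31 - 1).
subSeed <- function(seed, k) (as.numeric(seed) * 7919 + k * 104729) %% 2147483629

#' Species response parameters of the synthetic study
#'
#' One entry per study species encoding the qualitative drought-strategy
#' contrasts: base flux `S` (g cm-2 h-1), VPD half-saturation `v0` (hPa),
#' VPD activation threshold `vpdThresh` (hPa, below which stomata are
#' closed — this pins nocturnal flux to zero so the zero-flow TDP baseline
#' is identifiable), logistic soil-moisture response (`swcDir` in
#' increasing/decreasing/flat, midpoint `swcMid` %, scale `swcScale` %),
#' diurnal phase lead of sap flux over VPD by moisture state (`leadWet`,
#' `leadDry`, hours — flux peaking before demand gives the clockwise
#' hysteresis), dry-state amplitude factor `dryAmp` (< 1: extra stomatal
#' closure under dry soil; > 1 allowed for the evergreen, whose deep roots
#' sustain flux), foliation month window, and the true normalized radial
#' profile (`mu`, `sigma`; the amplitude is fixed by normalization to the
#' outer 0--2 cm TDP span). The evergreen species has no radial truth: its
#' HFD measurement fails by design and the pipeline must substitute.
#'
#' @return named list of parameter lists.
#' @export
speciesDefaults <- function() {
  list(
    Ceiba = list(
      phenology = "stem-succulent deciduous", S = 12, v0 = 6, vpdThresh = 0.5,
      swcDir = "increasing", swcMid = 10, swcScale = 4,
      leadWet = 3, leadDry = 0, dryAmp = 0.85,
      foliation = c(12L, 6L), profileMu = 2, profileSigma = 1.2,
      hfd = TRUE
    ),
    Eriotheca = list(
      phenology = "deciduous", S = 14, v0 = 6, vpdThresh = 0.5,
      swcDir = "increasing", swcMid = 10, swcScale = 4,
      leadWet = 3, leadDry = 0, dryAmp = 0.85,
      foliation = c(1L, 6L), profileMu = 0, profileSigma = 2.5,
      hfd = TRUE
    ),
    Erythrina = list(
      phenology = "brevi-deciduous", S = 13, v0 = 7, vpdThresh = 0.5,
      swcDir = "increasing", swcMid = 11, swcScale = 4,
      leadWet = 2, leadDry = 0, dryAmp = 0.8,
      foliation = c(1L, 6L), profileMu = 1, profileSigma = 2,
      hfd = TRUE
    ),
    Capparis = list(
      phenology = "evergreen", S = 26, v0 = 12, vpdThresh = 0.5,
      swcDir = "decreasing", swcMid = 15, swcScale = 25,
      leadWet = 4, leadDry = 3, dryAmp = 1.2,
      foliation = c(1L, 12L), profileMu = NA_real_,
      profileSigma = NA_real_, hfd = FALSE
    )
  )
}

## DBH means and SDs per species x elevation (cm) of the study design.
DBH_TABLE <- list(
  Ceiba = list(`670` = c(65.3, 2.3), `860` = c(69.9, 3.1), `1100` = c(99.6, 4.3)),
  Eriotheca = list(`670` = c(39.4, 2.1), `860` = c(34, 2.6), `1100` = c(44.4, 3.3)),
  Erythrina = list(`670` = c(32.5, 3.1), `860` = c(28.6, 3.7), `1100` = c(23.5, 2.1)),
  Capparis = list(`670` = c(21.5, 2.6), `860` = c(18.7, 2.3))
)

#' Default synthetic-study configuration
#'
#' The stated world: three elevations (670/860/1100 m), four species with
#' four trees each except no evergreen at the top site (44 trees), a
#' January--June wet-season study window, soil moisture increasing with
#' elevation with a classifiable two-week dry spell (January) and wet spell
#' (late March--April) at every site, diurnal temperature/humidity cycles
#' around a 23.7 degC lowland mean with VPD peaking mid-afternoon, and TDP
#' sensor inversion noise of 0.05 K.
#'
#' @param from,to study date range.
#' @param treesPerSpecies trees per species per elevation.
#' @return nested configuration list (sections `dates`, `elevations`,
#'   `species`, `trees`, `sensors`, `flux`, `microclimate`, `analysis`).
#' @export
studyConfig <- function(from = "2015-01-01", to = "2015-06-30",
                        treesPerSpecies = 4L) {
  list(
    dates = list(from = from, to = to),
    elevations = c(670L, 860L, 1100L),
    species = speciesDefaults(),
    trees = list(perSpecies = treesPerSpecies, dbh = DBH_TABLE,
                 sizeFactorSdLog = 0.2),
    sensors = list(dTmaxMean = 10, dTmaxSd = 0.5, noiseSd = 0.05,
                   azimuthOffset = 0.03),
    flux = list(noiseSdLog = 0.15, defoliatedResidual = 0.015),
    microclimate = list(
      tLowland = 23.7, lapseRate = 0.0065, tAmp = 5,
      rhBase = 99, rhAmpBase = 25, rhAmpWeather = 30, rhBumpExp = 3,
      rhNoiseSd = 1.2, tNoiseSd = 0.3,
      weatherSdLog = 0.25,
      swcNoiseSd = 1.2, swcAr = 0.8,
      ## SWC seasonal envelope anchors (day-of-year -> %vol) per elevation
      swcAnchorDoy = c(1, 32, 60, 79, 115, 130, 152, 181),
      swcAnchors = list(
        `670` = c(6, 8, 17, 29, 29, 11, 12, 12),
        `860` = c(8, 12, 22, 31, 31, 13, 15, 15),
        `1100` = c(10, 13, 28, 36, 36, 20, 27, 27)
      ),
      ## monthly daily probability and mean size (%) of rain pulses
      pulseProb = c(0, 0.10, 0.25, 0.25, 0.10, 0.05),
      pulseMean = 2.5, pulseDecayDays = 5
    ),
    analysis = list(dryThresh = 15, wetThresh = 25, windowDays = 14,
                    minCoverage = 0.8, baselineWindowDays = 10,
                    granierA = GRANIER_A, granierB = GRANIER_B)
  )
}

## normalized Gaussian profile amplitude: mean over the 0.5/1.5 cm points = 1
profileAmplitude <- function(mu, sigma) {
   2 / (exp(-(0.5 - mu)^2 / (2 * sigma^2)) + exp(-(1.5 - mu)^2 / (2 * sigma^2)))
}

#' Generate half-hourly microclimate for one site
#'
#' Temperature as a diurnal sinusoid around the lapse-adjusted lowland mean,
#' relative humidity anti-phased with a mid-afternoon dryness peak (so VPD
#' peaks around 15:30), and daily soil water content as a seasonal envelope
#' (wet-season rise, elevation-ordered) plus AR(1) weather noise and
#' stochastic rain pulses with exponential drydown. Each day carries a
#' lognormal "weather" factor (cloudiness) scaling the diurnal amplitudes.
#' The humidity channels of the lowest site are adopted from the mid
#' elevation (the study design's channel aliasing), which
#' [simulateStudy()] applies after generating each site.
#'
#' @param elevation one of 670, 860, 1100 (m asl).
#' @param from,to date range.
#' @param seed integer seed.
#' @param config `microclimate` section of [studyConfig()].
#' @return data.frame: `time`, `site`, `T`, `RH`, `SWC` (half-hourly).
#' @export
genMicroclimate <- function(elevation, from, to, seed,
                            config = studyConfig()$microclimate) {
  set.seed(seed)
  cfg <- config
  tm <- halfHourlyGrid(from, to)
  n <- length(tm)
  days <- seq(as.Date(from), as.Date(to), by = "day")
  nd <- length(days)
  dayIdx <- as.integer(dateOf(tm) - days[1]) + 1L
  h <- hourOf(tm)

  weather <- clamp(rlnorm(nd, 0, cfg$weatherSdLog), 0.4, 1.8)
  w <- weather[dayIdx]

  t0 <- cfg$tLowland - cfg$lapseRate * (elevation - 670)
  temp <- t0 + cfg$tAmp * w * cos(2 * pi * (h - 14.5) / 24) +
    rnorm(n, 0, cfg$tNoiseSd)

  dry <- ((1 + cos(2 * pi * (h - 15.5) / 24)) / 2)^(cfg$rhBumpExp %||% 3)
  rh <- cfg$rhBase - (cfg$rhAmpBase + cfg$rhAmpWeather * w) * dry +
    rnorm(n, 0, cfg$rhNoiseSd)
  rh <- clamp(rh, 5, 100)

  doy <- as.integer(format(days, "%j"))
  anchors <- cfg$swcAnchors[[as.character(elevation)]]
  env <- stats::approx(cfg$swcAnchorDoy, anchors, xout = doy, rule = 2)$y
  ar <- numeric(nd)
  innov <- rnorm(nd, 0, cfg$swcNoiseSd * sqrt(1 - cfg$swcAr^2))
  ar[1] <- rnorm(1, 0, cfg$swcNoiseSd)
  for (i in 2:nd) ar[i] <- cfg$swcAr * ar[i - 1] + innov[i]
  mon <- as.integer(format(days, "%m"))
  pp <- cfg$pulseProb[clamp(mon, 1, length(cfg$pulseProb))]
  pulseDay <- runif(nd) < pp
  pulseAmp <- ifelse(pulseDay, stats::rexp(nd, 1 / cfg$pulseMean), 0)
  pulse <- numeric(nd)
  for (i in seq_len(nd)) {
    if (pulseAmp[i] > 0) {
      j <- i:min(nd, i + 6L * cfg$pulseDecayDays)
      pulse[j] <- pulse[j] + pulseAmp[i] * exp(-(j - i) / cfg$pulseDecayDays)
    }
  }
  swcDaily <- clamp(env + ar + pulse, 3, 45)
  data.frame(time = tm, site = as.character(elevation),
             T = temp, RH = rh, SWC = swcDaily[dayIdx])
}

logisticSwc <- function(swc, dir, mid, scale) {
  switch(dir,
    increasing = 1 / (1 + exp(-(swc - mid) / scale)),
    decreasing = 1 / (1 + exp((swc - mid) / scale)),
    flat = rep(1, length(swc)),
    stop("unknown SWC response direction")
  )
}

## shift a series so that x(t) becomes x(t + lead hours) (flux anticipates
## demand); edge-padded with the last value
leadSeries <- function(x, leadHours) {
  k <- round(leadHours * 2)
  if (k == 0) return(x)
  n <- length(x)
  c(x[(k + 1):n], rep(x[n], k))
}

#' Generate a tree's true sap flux density series
#'
#' \deqn{J_s(t) = S \cdot s_f \cdot \left[1 - e^{-(VPD(t+\tau) - v_t)_+ / v_0}\right]
#'   \cdot g(SWC) \cdot foliage(t) \cdot a_{dry}(t) \cdot \epsilon(t)}
#' with \eqn{s_f} a per-tree lognormal size factor, the saturating VPD
#' response applied to the phase-advanced, thresholded VPD, `g` the
#' logistic soil-moisture response, the foliage switch (defoliated days
#' carry a small residual), the dry-state amplitude factor on days with
#' SWC < 15 %, and multiplicative lognormal noise with mean 1.
#'
#' @param params one species entry of [speciesDefaults()].
#' @param climate site microclimate ([genMicroclimate()] plus a `VPD`
#'   column).
#' @param seed integer seed (noise only).
#' @param sizeFactor per-tree multiplier (default 1).
#' @param noiseSdLog lognormal sigma of the multiplicative noise; 0 gives
#'   the deterministic response surface.
#' @param dryStateThresh SWC (%) below which the dry-state amplitude and
#'   lag apply.
#' @return numeric true Js (g cm-2 h-1) aligned with `climate$time`.
#' @export
genTrueFlux <- function(params, climate, seed, sizeFactor = 1,
                        noiseSdLog = 0.15, dryStateThresh = 15) {
  set.seed(seed)
  stopifnot(!is.null(climate$VPD))
  n <- nrow(climate)
  dates <- dateOf(climate$time)
  dryState <- climate$SWC < dryStateThresh
  vpdW <- leadSeries(climate$VPD, params$leadWet)
  vpdD <- leadSeries(climate$VPD, params$leadDry)
  vpdEff <- ifelse(dryState, vpdD, vpdW)
  sat <- 1 - exp(-pmax(vpdEff - params$vpdThresh, 0) / params$v0)
  g <- logisticSwc(climate$SWC, params$swcDir, params$swcMid, params$swcScale)
  fol <- ifelse(inFoliationWindow(dates, params$foliation), 1,
                studyConfig()$flux$defoliatedResidual)
  amp <- ifelse(dryState, params$dryAmp, 1)
  noise <- if (noiseSdLog > 0)
    rlnorm(n, -noiseSdLog^2 / 2, noiseSdLog) else rep(1, n)
  params$S * sizeFactor * sat * g * fol * amp * noise
}

#' Invert true sap flux to a pair of TDP sensor signals
#'
#' Inverts the Granier calibration, \eqn{K = (J_s/a)^{1/b}},
#' \eqn{\Delta T = \Delta T_{max}/(1 + K)}, producing north and south
#' azimuth signals with a small multiplicative flux offset between them
#' (azimuthal flow asymmetry) and additive Gaussian sensor noise on
#' \eqn{\Delta T}.
#'
#' @param js true sap flux density series.
#' @param dTmaxNorth,dTmaxSouth per-sensor zero-flow baselines, K.
#' @param noiseSd additive noise SD on the differential, K.
#' @param seed integer seed.
#' @param azimuthOffset relative flux offset delta: north carries
#'   `(1+delta)`, south `(1-delta)` times the true flux.
#' @param a,b Granier coefficients.
#' @return data.frame: `north`, `south` (Delta-T, K).
#' @export
invertToSensorSignals <- function(js, dTmaxNorth, dTmaxSouth,
                                  noiseSd = 0.05, seed = 1,
                                  azimuthOffset = 0.03,
                                  a = GRANIER_A, b = GRANIER_B) {
  set.seed(seed)
  stopifnot(all(js >= 0))
  n <- length(js)
  one <- function(jsAz, dTmax) {
    K <- (jsAz / a)^(1 / b)
    dT <- dTmax / (1 + K)
    if (noiseSd > 0) dT <- dT + rnorm(n, 0, noiseSd)
    pmax(dT, 0.05)
  }
  data.frame(
    north = one(js * (1 + azimuthOffset), dTmaxNorth),
    south = one(js * (1 - azimuthOffset), dTmaxSouth)
  )
}

#' Generate noisy HFD radial profile observations
#'
#' Samples the species' true Gaussian depth profile at the eight 1-cm bin
#' midpoints, scales it to flux units, and adds Gaussian observation noise.
#'
#' @param params species entry of [speciesDefaults()] (needs `profileMu`,
#'   `profileSigma`).
#' @param depths observation depths, cm.
#' @param fluxScale flux at the normalization reference (g cm-2 h-1).
#' @param noiseSd relative observation noise SD (fraction of `fluxScale`).
#' @param seed integer seed.
#' @return data.frame: `depth`, `value`.
#' @export
genRadialObservations <- function(params, depths = HFD_DEPTHS,
                                  fluxScale = 5, noiseSd = 0.05, seed = 1) {
  set.seed(seed)
  if (!isTRUE(params$hfd)) stop("species has no HFD profile truth")
  A <- profileAmplitude(params$profileMu, params$profileSigma)
  f <- A * exp(-(depths - params$profileMu)^2 / (2 * params$profileSigma^2))
  v <- fluxScale * (f + rnorm(length(depths), 0, noiseSd))
  data.frame(depth = depths, value = pmax(v, 0))
}

#' Simulate the full synthetic study
#'
#' Draws one realization of the study design under `config`: tree cohort
#' with DBH from the design's species x elevation distributions, per-site
#' microclimate (the lowest site adopting mid-elevation humidity), true
#' per-tree flux surfaces, inverted noisy TDP signals, and HFD radial
#' observations for the three species with working sensors. All ground
#' truth is retained.
#'
#' @param config configuration from [studyConfig()].
#' @param seed master integer seed; all stages derive sub-seeds from it.
#' @return a [SyntheticStudy-class] object.
#' @export
simulateStudy <- function(config = studyConfig(), seed = 1) {
  seed <- as.integer(seed)
  from <- config$dates$from; to <- config$dates$to

  ## microclimate per elevation; lowest site adopts mid-elevation humidity
  climate <- lapply(seq_along(config$elevations), function(i) {
    genMicroclimate(config$elevations[i], from, to,
                    seed = subSeed(seed, i), config = config$microclimate)
  })
  names(climate) <- as.character(config$elevations)
  climate[["670"]]$T <- climate[["860"]]$T
  climate[["670"]]$RH <- climate[["860"]]$RH
  for (el in names(climate))
    climate[[el]]$VPD <- computeVPD(climate[[el]]$T, climate[[el]]$RH)

  ## tree cohort
  set.seed(subSeed(seed, 100))
  rows <- list()
  for (el in config$elevations) {
    for (sp in names(config$species)) {
      dbhPar <- config$trees$dbh[[sp]][[as.character(el)]]
      if (is.null(dbhPar)) next  # no evergreen at the top site
      for (k in seq_len(config$trees$perSpecies)) {
        rows[[length(rows) + 1]] <- data.frame(
          tree = sprintf("%s_%d_%d", sp, el, k), species = sp,
          phenology = config$species[[sp]]$phenology,
          elevation = el,
          dbh = max(16, rnorm(1, dbhPar[1], dbhPar[2])),
          sizeFactor = rlnorm(1, 0, config$trees$sizeFactorSdLog)
        )
      }
    }
  }
  trees <- do.call(rbind, rows)

  ## per-sensor zero-flow baselines
  set.seed(subSeed(seed, 200))
  dTmax <- data.frame(
    tree = rep(trees$tree, each = 2),
    azimuth = rep(c("north", "south"), nrow(trees)),
    dTmax = clamp(rnorm(2 * nrow(trees), config$sensors$dTmaxMean,
                        config$sensors$dTmaxSd), 8, 12)
  )

  ## true flux and sensor inversion
  fluxList <- vector("list", nrow(trees))
  sensorList <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    cl <- climate[[as.character(tr$elevation)]]
    js <- genTrueFlux(config$species[[tr$species]], cl,
                      seed = subSeed(seed, 1000 + i),
                      sizeFactor = tr$sizeFactor,
                      noiseSdLog = config$flux$noiseSdLog)
    fluxList[[i]] <- data.frame(time = cl$time, tree = tr$tree, js = js)
    bl <- dTmax[dTmax$tree == tr$tree, ]
    sig <- invertToSensorSignals(
      js, bl$dTmax[bl$azimuth == "north"], bl$dTmax[bl$azimuth == "south"],
      noiseSd = config$sensors$noiseSd, seed = subSeed(seed, 2000 + i),
      azimuthOffset = config$sensors$azimuthOffset
    )
    sensorList[[i]] <- data.frame(
      time = rep(cl$time, 2), tree = tr$tree,
      azimuth = rep(c("north", "south"), each = nrow(cl)),
      dT = c(sig$north, sig$south)
    )
  }

  ## HFD radial observations (fail for the evergreen by design)
  profList <- list()
  trueProf <- list()
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    sp <- config$species[[tr$species]]
    if (!isTRUE(sp$hfd)) next
    obs <- genRadialObservations(
      sp, fluxScale = 5 * tr$sizeFactor,
      noiseSd = 0.05, seed = subSeed(seed, 3000 + i)
    )
    profList[[length(profList) + 1]] <- data.frame(
      tree = tr$tree, species = tr$species, obs
    )
  }
  for (sp in names(config$species)) {
    p <- config$species[[sp]]
    if (!isTRUE(p$hfd)) next
    trueProf[[sp]] <- c(
      A = profileAmplitude(p$profileMu, p$profileSigma),
      mu = p$profileMu, sigma = p$profileSigma
    )
  }

  new("SyntheticStudy",
    config = config, seed = seed, trees = trees,
    climate = do.call(rbind, c(climate, list(make.row.names = FALSE))),
    sensors = do.call(rbind, c(sensorList, list(make.row.names = FALSE))),
    profiles = do.call(rbind, c(profList, list(make.row.names = FALSE))),
    truth = list(
      flux = do.call(rbind, c(fluxList, list(make.row.names = FALSE))),
      dTmax = dTmax,
      profiles = trueProf,
      speciesParams = config$species
    )
  )
}

#' Write the synthetic study as a CSV fixture tree
#'
#' Emits the raw files the pipeline consumes (`climate.csv` long format
#' with columns timestamp/site/channel/value, `sensors.csv`,
#' `profiles.csv`, `trees.csv`), the ground truth (`truth_flux.csv`,
#' `truth.json`), the configuration snapshot (`config.json`) and a
#' `manifest.json` listing every file with its md5 checksum.
#'
#' @param study a [SyntheticStudy-class] from [simulateStudy()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
writeFixtureDataset <- function(study, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmtTime <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  cl <- study@climate
  climLong <- data.table::rbindlist(lapply(c("T", "RH", "SWC"), function(ch)
    data.frame(timestamp = fmtTime(cl$time), site = cl$site, channel = ch,
               value = round(cl[[ch]], 4))))
  data.table::fwrite(climLong, file.path(dir, "climate.csv"))

  sn <- study@sensors
  data.table::fwrite(
    data.frame(timestamp = fmtTime(sn$time), tree = sn$tree,
               azimuth = sn$azimuth, dT = round(sn$dT, 5)),
    file.path(dir, "sensors.csv")
  )
  data.table::fwrite(study@profiles, file.path(dir, "profiles.csv"))
  data.table::fwrite(
    study@trees[, c("tree", "species", "phenology", "elevation", "dbh")],
    file.path(dir, "trees.csv")
  )
  fl <- study@truth$flux
  data.table::fwrite(
    data.frame(timestamp = fmtTime(fl$time), tree = fl$tree,
               js = round(fl$js, 6)),
    file.path(dir, "truth_flux.csv")
  )
  jsonlite::write_json(
    list(seed = study@seed, dTmax = study@truth$dTmax,
         profiles = study@truth$profiles),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(study@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(dir(dir), "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
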