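# run the full processing chain on a SyntheticStudy in memory, using only
# exported package functions (the same wiring as the pipeline stages)
processStudy <- function(study) {
  cfg <- study@config
  climate <- split(studyClimate(study), studyClimate(study)$site)
  vpdSeries <- lapply(climate, function(cl)
    halfHourlySeries(cl$time, cl$VPD, "VPD", site = cl$site[1]))
  drivers <- lapply(names(climate), function(site) {
    cl <- climate[[site]]
    dailyDrivers(halfHourlySeries(cl$time, cl$SWC, "SWC", site = site),
                 vpdSeries[[site]])
  })
  names(drivers) <- names(climate)
  periods <- suppressWarnings(lapply(drivers, classifyMoisturePeriods))

  trees <- studyTrees(study)
  trees$elevation <- as.character(trees$elevation)
  sensors <- split(studySensors(study), studySensors(study)$tree)
  daily <- list(); fluxSeries <- list()
  for (tr in trees$tree) {
    azs <- lapply(split(sensors[[tr]], sensors[[tr]]$azimuth), function(s) {
      s <- s[order(s$time), ]
      sensorFlux(halfHourlySeries(s$time, s$dT, "dT", tree = tr))
    })
    fl <- combineAzimuths(azs[[1]], azs[[2]])
    fl@tree <- tr
    fluxSeries[[tr]] <- fl
    sp <- trees$species[match(tr, trees$tree)]
    daily[[tr]] <- summarizeDaily(fl, cfg$species[[sp]]$foliation)
  }
  daily <- do.call(rbind, c(daily, list(make.row.names = FALSE)))

  # radial fits and geometry (evergreen substituted from the donor)
  prof <- study@profiles
  fits <- lapply(unique(prof$tree), function(tr) {
    sub <- prof[prof$tree == tr, ]
    np <- normalizeProfile(sub$depth, sub$value, tree = tr)
    fitGaussianProfile(np$depths, np$values, tree = tr,
                       species = sub$species[1])
  })
  spFits <- list()
  for (sp in unique(trees$species)) {
    spFits[[sp]] <- if (isTRUE(cfg$species[[sp]]$hfd))
      substituteProfile(sp, sp, fits)
    else substituteProfile(sp, "Erythrina", fits)
  }
  geo <- stemGeometry(trees$dbh)
  geometry <- data.frame(tree = trees$tree, R = geo$R, D = geo$D)
  geometry$Aeff <- vapply(seq_len(nrow(geometry)), function(i)
    conductingArea(spFits[[trees$species[i]]], geometry$R[i], geometry$D[i]),
    numeric(1))

  meta <- trees[, c("tree", "species", "elevation", "dbh")]
  tbl <- suppressMessages(
    buildAnalysisTable(daily, drivers, meta, periods))
  wu <- wholeTreeWaterUse(daily, geometry)

  # hysteresis: one wet and one dry high-demand day per site
  pickDay <- function(site, lab) {
    d <- drivers[[site]]
    if (!nrow(periods[[site]])) return(as.Date(NA))
    d <- d[moistureLabel(d$date, periods[[site]]) == lab & d$valid, ]
    if (!nrow(d)) return(as.Date(NA))
    d$date[which.max(d$vpdMax)]
  }
  wetLoops <- list(); dryLoops <- list()
  for (site in names(climate)) {
    for (sp in unique(trees$species[trees$elevation == site])) {
      ids <- trees$tree[trees$elevation == site & trees$species == sp]
      grp <- averageSeries(fluxSeries[ids])
      g <- paste(sp, site, sep = "_")
      for (lab in c("wet", "dry")) {
        day <- pickDay(site, lab)
        if (is.na(day)) next
        lp <- tryCatch(buildLoop(grp, vpdSeries[[site]], day, group = g),
                       error = function(e) NULL)
        if (lab == "wet") wetLoops[[g]] <- lp else dryLoops[[g]] <- lp
      }
    }
  }
  loopCmp <- compareWetDryLoops(Filter(Negate(is.null), wetLoops),
                                Filter(Negate(is.null), dryLoops))

  list(trees = trees, drivers = drivers, periods = periods, daily = daily,
       table = tbl, geometry = geometry, wu = wu, loops = loopCmp,
       fluxSeries = fluxSeries, speciesFits = spFits)
}
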