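PIPELINE_STAGES <- c("simulate", "microclimate", "flux", "radial",
                     "wateruse", "stats", "hysteresis")

stageInputs <- function(stage) {
  switch(stage,
    simulate = character(),
    microclimate = "raw/climate.csv",
    flux = c("raw/sensors.csv", "raw/trees.csv", "raw/config.json"),
    radial = c("raw/profiles.csv", "raw/trees.csv"),
    wateruse = c("daily_flux.csv", "geometry.csv",
                 "drivers.csv", "periods.csv", "raw/trees.csv"),
    stats = c("daily_flux.csv", "drivers.csv", "periods.csv",
              "raw/trees.csv"),
    hysteresis = c("flux_halfhourly.csv", "raw/climate.csv", "periods.csv",
                   "drivers.csv", "raw/trees.csv")
  )
}

#' Run the analysis pipeline
#'
#' Executes the processing stages in dependency order inside `outDir`:
#' `simulate` (synthetic raw data under `outDir/raw/`), `microclimate`
#' (daily drivers and moisture periods per site), `flux` (TDP conversion
#' and daily per-tree summaries), `radial` (profile fits and conducting
#' geometry), `wateruse` (whole-tree water use and DBH scaling), `stats`
#' (regressions, wet/dry summaries, mixed model, ls-means) and
#' `hysteresis` (wet/dry loop metrics). Any subset may be requested when
#' the upstream outputs already exist; a missing upstream file raises an
#' error naming it. A `manifest.json` records the configuration snapshot,
#' md5 checksums of every input and output file, stage counters/warnings
#' and a timestamp — all tabular outputs are deterministic for a given
#' configuration and seed.
#'
#' @param outDir working directory for all inputs/outputs.
#' @param stages character vector of stage names, or `"all"`.
#' @param config generator/analysis configuration list ([studyConfig()]),
#'   or a path to a YAML/JSON file with the same structure.
#' @param seed seed for the `simulate` stage (other stages are
#'   deterministic); defaults to 1.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(outDir, stages = "all", config = studyConfig(),
                        seed = 1) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed to read YAML configuration")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counters <- list()
  outputs <- character()
  for (st in stages) {
    need <- file.path(outDir, stageInputs(st))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop(sprintf("stage '%s' requires missing upstream output(s): %s",
                   st, paste(basename(missing), collapse = ", ")))
    res <- switch(st,
      simulate = stageSimulate(outDir, config, seed),
      microclimate = stageMicroclimate(outDir, config),
      flux = stageFlux(outDir, config),
      radial = stageRadial(outDir, config),
      wateruse = stageWaterUse(outDir, config),
      stats = stageStats(outDir, config),
      hysteresis = stageHysteresis(outDir, config)
    )
    counters[[st]] <- res$counters
    outputs <- c(outputs, res$outputs)
  }
  allFiles <- unique(c(outputs, file.path("raw", dir(file.path(outDir, "raw")))))
  allFiles <- allFiles[file.exists(file.path(outDir, allFiles))]
  manifest <- list(
    config = config, seed = seed, stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"),
    counters = counters,
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(outDir, allFiles))), allFiles))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

stageSimulate <- function(outDir, config, seed) {
  study <- simulateStudy(config, seed)
  writeFixtureDataset(study, file.path(outDir, "raw"), force = TRUE)
  list(outputs = character(), counters = list(trees = nrow(study@trees)))
}

loadTrees <- function(outDir) {
  tr <- as.data.frame(data.table::fread(file.path(outDir, "raw/trees.csv")))
  tr$tree <- as.character(tr$tree)
  tr$elevation <- as.character(tr$elevation)
  tr
}

stageMicroclimate <- function(outDir, config) {
  clim <- readClimateCSV(file.path(outDir, "raw/climate.csv"))
  minCov <- config$analysis$minCoverage %||% 0.8
  drv <- list(); per <- list()
  for (site in names(clim)) {
    vpd <- computeVPD(clim[[site]]$T, clim[[site]]$RH)
    d <- dailyDrivers(clim[[site]]$SWC, vpd, minCoverage = minCov)
    d$site <- site
    p <- classifyMoisturePeriods(
      d, dryThresh = config$analysis$dryThresh %||% 15,
      wetThresh = config$analysis$wetThresh %||% 25,
      windowDays = config$analysis$windowDays %||% 14
    )
    if (nrow(p)) p$site <- site
    drv[[site]] <- d; per[[site]] <- p
  }
  drivers <- do.call(rbind, c(drv, list(make.row.names = FALSE)))
  periods <- do.call(rbind, c(per[vapply(per, nrow, 0L) > 0],
                              list(make.row.names = FALSE)))
  data.table::fwrite(drivers, file.path(outDir, "drivers.csv"))
  data.table::fwrite(periods, file.path(outDir, "periods.csv"))
  list(outputs = c("drivers.csv", "periods.csv"),
       counters = list(sites = length(clim), periods = nrow(periods)))
}

speciesFoliation <- function(config) {
  lapply(config$species, function(p) p$foliation)
}

stageFlux <- function(outDir, config) {
  sensors <- readSensorCSV(file.path(outDir, "raw/sensors.csv"))
  trees <- loadTrees(outDir)
  fol <- speciesFoliation(config)
  wd <- config$analysis$baselineWindowDays %||% 10
  minCov <- config$analysis$minCoverage %||% 0.8
  a <- config$analysis$granierA %||% GRANIER_A
  b <- config$analysis$granierB %||% GRANIER_B
  nClipped <- 0L
  hh <- list(); daily <- list()
  for (tr in names(sensors)) {
    az <- lapply(sensors[[tr]], sensorFlux, windowDays = wd, a = a, b = b)
    for (s in az) nClipped <- nClipped + attr(s, "nClipped")
    flux <- if (length(az) == 2) combineAzimuths(az[[1]], az[[2]]) else az[[1]]
    flux@tree <- tr
    sp <- trees$species[match(tr, trees$tree)]
    daily[[tr]] <- summarizeDaily(flux, unlist(fol[[sp]]), minCoverage = minCov)
    hh[[tr]] <- data.frame(
      timestamp = format(flux@time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      tree = tr, js = round(flux@values, 5)
    )
  }
  data.table::fwrite(data.table::rbindlist(hh),
                     file.path(outDir, "flux_halfhourly.csv"))
  data.table::fwrite(data.table::rbindlist(daily),
                     file.path(outDir, "daily_flux.csv"))
  list(outputs = c("flux_halfhourly.csv", "daily_flux.csv"),
       counters = list(trees = length(sensors), clippedRecords = nClipped))
}

stageRadial <- function(outDir, config) {
  prof <- as.data.frame(data.table::fread(file.path(outDir, "raw/profiles.csv")))
  trees <- loadTrees(outDir)
  fits <- list()
  for (tr in unique(prof$tree)) {
    sub <- prof[prof$tree == tr, ]
    np <- normalizeProfile(sub$depth, sub$value, tree = tr)
    fits[[tr]] <- fitGaussianProfile(np$depths, np$values, tree = tr,
                                     species = sub$species[1])
  }
  ## species-mean fits; species without any usable fit adopt a donor
  allSpecies <- unique(trees$species)
  measured <- unique(vapply(fits, function(f) f@species, character(1)))
  spFits <- list()
  for (sp in allSpecies) {
    spFits[[sp]] <- if (sp %in% measured) {
      substituteProfile(sp, sp, fits)
    } else {
      donor <- config$substitution[[sp]] %||% "Erythrina"
      substituteProfile(sp, donor, fits)
    }
  }
  nSub <- sum(vapply(spFits, function(f) f@substituted, logical(1)))
  fitTable <- do.call(rbind, lapply(names(spFits), function(sp) {
    f <- spFits[[sp]]
    data.frame(species = sp, A = f@A, mu = f@mu, sigma = f@sigma,
               r2 = f@r2, substituted = f@substituted)
  }))
  geo <- stemGeometry(trees$dbh,
                      barkAllowance = config$barkAllowance %||% 1,
                      maxDepth = config$maxDepth %||% 8)
  geometry <- data.frame(tree = trees$tree, species = trees$species,
                         R = geo$R, D = geo$D, Aeff = NA_real_)
  for (i in seq_len(nrow(geometry))) {
    geometry$Aeff[i] <- conductingArea(spFits[[geometry$species[i]]],
                                       geometry$R[i], geometry$D[i])
  }
  data.table::fwrite(fitTable, file.path(outDir, "profile_fits.csv"))
  data.table::fwrite(geometry, file.path(outDir, "geometry.csv"))
  list(outputs = c("profile_fits.csv", "geometry.csv"),
       counters = list(fits = length(fits), substitutedSpecies = nSub))
}

loadDailyFlux <- function(outDir) {
  d <- as.data.frame(data.table::fread(file.path(outDir, "daily_flux.csv")))
  d$tree <- as.character(d$tree)
  d$date <- as.Date(d$date)
  d
}

loadDrivers <- function(outDir) {
  d <- as.data.frame(data.table::fread(file.path(outDir, "drivers.csv")))
  d$date <- as.Date(d$date)
  split(d, as.character(d$site))
}

loadPeriods <- function(outDir) {
  p <- as.data.frame(data.table::fread(file.path(outDir, "periods.csv")))
  p$start <- as.Date(p$start); p$end <- as.Date(p$end)
  split(p, as.character(p$site))
}

stageWaterUse <- function(outDir, config) {
  daily <- loadDailyFlux(outDir)
  geometry <- as.data.frame(data.table::fread(file.path(outDir, "geometry.csv")))
  trees <- loadTrees(outDir)
  drivers <- loadDrivers(outDir)
  periods <- loadPeriods(outDir)
  wu <- wholeTreeWaterUse(daily, geometry)
  data.table::fwrite(wu, file.path(outDir, "wateruse.csv"))
  days <- unique(do.call(c, lapply(names(drivers), function(site) {
    if (is.null(periods[[site]])) return(as.Date(character()))
    sunnyWetDays(drivers[[site]], periods[[site]])
  })))
  scal <- fitDbhScaling(wu, trees, days = days)
  data.table::fwrite(
    data.frame(slope = scal$slope, intercept = scal$intercept,
               r2 = scal$r2, p = scal$p, n = scal$n),
    file.path(outDir, "dbh_scaling.csv")
  )
  list(outputs = c("wateruse.csv", "dbh_scaling.csv"),
       counters = list(nTrees = scal$n, skipped = attr(wu, "nSkipped")))
}

stageStats <- function(outDir, config) {
  daily <- loadDailyFlux(outDir)
  trees <- loadTrees(outDir)
  drivers <- loadDrivers(outDir)
  periods <- loadPeriods(outDir)
  meta <- data.frame(tree = trees$tree, species = trees$species,
                     elevation = trees$elevation, dbh = trees$dbh)
  tbl <- buildAnalysisTable(daily, drivers, meta, periods)
  data.table::fwrite(tbl, file.path(outDir, "analysis_table.csv"))

  groups <- unique(tbl[c("species", "elevation")])
  reg <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- tbl[tbl$species == groups$species[i] &
               tbl$elevation == groups$elevation[i], ]
    sw <- tryCatch(regressFluxOnSWC(sub), error = function(e) NULL)
    rows <- list()
    if (!is.null(sw)) rows$swc <- data.frame(
      species = groups$species[i], elevation = groups$elevation[i],
      driver = "SWC", label = "all", slope = sw$slope, r2 = sw$r2,
      p = sw$p, n = sw$n)
    for (lb in c("wet", "dry")) {
      vp <- tryCatch(regressFluxOnVPD(sub, lb), error = function(e) NULL)
      if (!is.null(vp)) rows[[lb]] <- data.frame(
        species = groups$species[i], elevation = groups$elevation[i],
        driver = "lnVPD", label = lb, slope = vp$b, r2 = vp$r2,
        p = vp$p, n = vp$n)
    }
    do.call(rbind, rows)
  }))
  data.table::fwrite(reg, file.path(outDir, "regressions.csv"))

  jm <- tryCatch(jsmaxSummary(tbl), error = function(e) NULL)
  if (!is.null(jm)) data.table::fwrite(jm, file.path(outDir, "jsmax.csv"))

  mm <- fitMixedModel(tbl)
  av <- anovaTable(mm)
  av <- cbind(term = rownames(av), av)
  data.table::fwrite(av, file.path(outDir, "anova.csv"))
  data.table::fwrite(
    data.frame(r2m = mm@r2m, r2c = mm@r2c,
               varTree = mm@varcomp[["tree"]],
               varResid = mm@varcomp[["residual"]]),
    file.path(outDir, "r2.csv")
  )
  ls <- rbind(
    cbind(focus = "SWC", lsMeans(mm, "SWC")),
    cbind(focus = "VPD", lsMeans(mm, "VPD")),
    cbind(focus = "mean", lsMeans(mm, "mean"))
  )
  data.table::fwrite(ls, file.path(outDir, "lsmeans.csv"))
  list(outputs = c("analysis_table.csv", "regressions.csv", "jsmax.csv",
                   "anova.csv", "r2.csv", "lsmeans.csv"),
       counters = list(rows = nrow(tbl), dropped = attr(tbl, "nDropped")))
}

stageHysteresis <- function(outDir, config) {
  hh <- as.data.frame(data.table::fread(file.path(outDir, "flux_halfhourly.csv")))
  hh$time <- parseTime(hh$timestamp)
  trees <- loadTrees(outDir)
  clim <- readClimateCSV(file.path(outDir, "raw/climate.csv"))
  drivers <- loadDrivers(outDir)
  periods <- loadPeriods(outDir)

  pickDay <- function(site, lab) {
    d <- drivers[[site]]
    p <- periods[[site]]
    if (is.null(p)) return(as.Date(NA))
    d <- d[moistureLabel(d$date, p) == lab & d$valid, ]
    if (!nrow(d)) return(as.Date(NA))
    d$date[which.max(d$vpdMax)]
  }

  wetLoops <- list(); dryLoops <- list(); rows <- list()
  for (site in names(clim)) {
    vpd <- computeVPD(clim[[site]]$T, clim[[site]]$RH)
    dayW <- pickDay(site, "wet"); dayD <- pickDay(site, "dry")
    siteTrees <- trees[trees$elevation == site, ]
    for (sp in unique(siteTrees$species)) {
      ids <- siteTrees$tree[siteTrees$species == sp]
      sl <- lapply(ids, function(id) {
        sub <- hh[hh$tree == id, ]
        sub <- sub[order(sub$time), ]
        halfHourlySeries(sub$time, sub$js, "Js", tree = id, site = site)
      })
      grp <- averageSeries(sl)
      g <- paste(sp, site, sep = "_")
      if (!is.na(dayW))
        wetLoops[[g]] <- tryCatch(buildLoop(grp, vpd, dayW, group = g),
                                  error = function(e) NULL)
      if (!is.na(dayD))
        dryLoops[[g]] <- tryCatch(buildLoop(grp, vpd, dayD, group = g),
                                  error = function(e) NULL)
      for (lp in list(wetLoops[[g]], dryLoops[[g]])) {
        if (is.null(lp)) next
        rows[[length(rows) + 1]] <- cbind(loopMetrics(lp), species = sp,
                                          site = site)
      }
    }
  }
  wetLoops <- Filter(Negate(is.null), wetLoops)
  dryLoops <- Filter(Negate(is.null), dryLoops)
  cmp <- compareWetDryLoops(wetLoops, dryLoops)
  data.table::fwrite(do.call(rbind, rows), file.path(outDir, "loops.csv"))
  data.table::fwrite(cmp, file.path(outDir, "loop_contrasts.csv"))
  list(outputs = c("loops.csv", "loop_contrasts.csv"),
       counters = list(groups = nrow(cmp)))
}
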