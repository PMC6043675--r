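#' Simulate a daily analysis table directly from the mixed model
#'
#' Draws a tree-day table straight from the linear mixed model the package
#' fits — covariates with the study's structure (elevation-ordered AR(1)
#' soil moisture, lognormal daily VPD, species/elevation factors, DBH per
#' species cell), a known fixed-effect vector in the model's own coding
#' (sum-to-zero contrasts, centred covariates), a per-tree random intercept
#' and i.i.d. residuals. This is the calibration harness for the mixed
#' model: with `beta = NULL` all fixed effects except the intercept are
#' zero (type-I error studies); any named subset of design columns can be
#' set for power/coverage studies.
#'
#' @param nTrees number of trees, allocated round-robin over the 4 x 3
#'   species/elevation grid (all cells filled, unlike the field design, so
#'   the design is full rank).
#' @param nDays days per tree.
#' @param beta named numeric of true fixed-effect coefficients (names must
#'   match the design columns, e.g. `"VPD"`, `"SWC:species1"`); unnamed
#'   columns are zero. `NULL` = all-null with intercept 5.
#' @param sdTree,sdResid random-intercept and residual SDs.
#' @param seed integer seed.
#' @return list: `table` (analysis-table columns), `beta` (the full true
#'   coefficient vector over the design columns), `design` (the model
#'   matrix used), `sdTree`, `sdResid`.
#' @export
simulateResponseTable <- function(nTrees = 40, nDays = 150, beta = NULL,
                                  sdTree = 1, sdResid = 1, seed = 1) {
  set.seed(as.integer(seed))
  species <- c("Ceiba", "Eriotheca", "Erythrina", "Capparis")
  elevations <- c(670L, 860L, 1100L)
  cells <- expand.grid(species = species, elevation = elevations,
                       stringsAsFactors = FALSE)
  cellIdx <- rep_len(seq_len(nrow(cells)), nTrees)
  dbhMean <- c(Ceiba = 70, Eriotheca = 39, Erythrina = 30, Capparis = 20)

  ## site-level daily drivers: SWC ordered by elevation, shared VPD weather
  swcBase <- c(`670` = 15, `860` = 20, `1100` = 27)
  drv <- lapply(as.character(elevations), function(el) {
    ar <- numeric(nDays)
    ar[1] <- rnorm(1, 0, 4)
    for (i in 2:nDays) ar[i] <- 0.8 * ar[i - 1] + rnorm(1, 0, 4 * sqrt(0.36))
    data.frame(
      day = seq_len(nDays),
      swcMean = clamp(swcBase[[el]] + ar, 3, 45),
      vpdMean = rlnorm(nDays, log(8), 0.4)
    )
  })
  names(drv) <- as.character(elevations)

  rows <- lapply(seq_len(nTrees), function(i) {
    sp <- cells$species[cellIdx[i]]; el <- cells$elevation[cellIdx[i]]
    d <- drv[[as.character(el)]]
    data.frame(
      tree = sprintf("t%02d", i), species = sp, elevation = el,
      dbh = max(16, rnorm(1, dbhMean[[sp]], 4)),
      date = as.Date("2015-01-01") + d$day - 1,
      swcMean = d$swcMean, vpdMean = d$vpdMean
    )
  })
  tbl <- do.call(rbind, rows)
  tbl$jsMean <- 0  # placeholder for the design pass

  des <- mixedDesign(tbl, center = TRUE)
  X <- model.matrix(fixedFormula()[-2], des$data)
  fullBeta <- setNames(numeric(ncol(X)), colnames(X))
  fullBeta["(Intercept)"] <- 5
  if (!is.null(beta)) {
    bad <- setdiff(names(beta), colnames(X))
    if (length(bad)) stop("unknown design columns: ", paste(bad, collapse = ", "))
    fullBeta[names(beta)] <- beta
  }
  b <- rnorm(nTrees, 0, sdTree)
  y <- as.vector(X %*% fullBeta) +
    b[match(tbl$tree, sprintf("t%02d", seq_len(nTrees)))] +
    rnorm(nrow(tbl), 0, sdResid)
  tbl$jsMean <- y
  tbl$jsMax <- y
  list(table = tbl, beta = fullBeta, design = X,
       sdTree = sdTree, sdResid = sdResid)
}
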