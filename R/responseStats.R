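#' Assemble the per-tree-day analysis table
#'
#' Inner join of the daily per-tree flux summaries, the daily drivers of the
#' tree's site, and the tree metadata, plus the moisture-period label.
#' Rows with a missing driver or flux are dropped (counts reported via
#' attribute `nDropped`). With `maskDefoliated = TRUE` (default),
#' tree-days outside the tree's foliation window are excluded: the
#' near-zero flux of a leafless deciduous tree would otherwise manufacture
#' spurious soil-moisture correlations.
#'
#' @param daily per-tree daily summaries (rows of [summarizeDaily()]).
#' @param drivers named list of daily driver tables ([dailyDrivers()]), one
#'   per site, names = site labels; or a single table used for all trees.
#' @param meta tree metadata: `tree`, `species`, `elevation`, `dbh`
#'   (`elevation` must name an entry of `drivers`).
#' @param periods named list of moisture-period tables per site (or a single
#'   table), used for the `label` column; `NULL` labels all days "neither".
#' @param maskDefoliated drop defoliated tree-days.
#' @return data.frame: `tree`, `species`, `elevation`, `dbh`, `date`,
#'   `jsMean`, `jsMax`, `jsSum`, `swcMean`, `vpdMean`, `vpdMax`, `label`,
#'   `foliated`; attribute `nDropped`.
#' @export
buildAnalysisTable <- function(daily, drivers, meta, periods = NULL,
                               maskDefoliated = TRUE) {
  stopifnot(all(c("tree", "species", "elevation", "dbh") %in% names(meta)))
  m <- match(daily$tree, meta$tree)
  if (anyNA(m)) stop("trees missing from metadata: ",
                     paste(unique(daily$tree[is.na(m)]), collapse = ", "))
  tbl <- cbind(daily, meta[m, c("species", "elevation", "dbh")])
  oneSite <- is.data.frame(drivers)
  if (!oneSite && !all(as.character(tbl$elevation) %in% names(drivers)))
    stop("driver tables missing for elevation(s): ",
         paste(setdiff(unique(as.character(tbl$elevation)), names(drivers)),
               collapse = ", "))
  n0 <- nrow(tbl)
  parts <- lapply(split(tbl, as.character(tbl$elevation)), function(sub) {
    el <- as.character(sub$elevation[1])
    drv <- if (oneSite) drivers else drivers[[el]]
    i <- match(sub$date, drv$date)
    sub$swcMean <- drv$swcMean[i]
    sub$vpdMean <- drv$vpdMean[i]
    sub$vpdMax <- drv$vpdMax[i]
    per <- if (is.null(periods)) NULL
           else if (is.data.frame(periods)) periods else periods[[el]]
    sub$label <- if (is.null(per)) "neither" else moistureLabel(sub$date, per)
    sub
  })
  tbl <- do.call(rbind, parts)
  rownames(tbl) <- NULL
  keep <- is.finite(tbl$jsMean) & is.finite(tbl$swcMean) &
    is.finite(tbl$vpdMean)
  if (maskDefoliated) keep <- keep & tbl$foliated
  out <- tbl[keep, , drop = FALSE]
  nDropped <- n0 - nrow(out)
  if (nDropped) message(nDropped, " tree-days dropped (missing data",
                        if (maskDefoliated) " or defoliated", ")")
  attr(out, "nDropped") <- nDropped
  out
}

#' Linear regression of daily sap flux on soil water content
#'
#' OLS of daily mean sap flux density on daily mean SWC, typically within
#' one species x elevation subset: the day-to-day soil-moisture response.
#'
#' @param tbl analysis-table subset (needs `jsMean`, `swcMean`), >= 10 rows.
#' @return list: `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
regressFluxOnSWC <- function(tbl) {
  tbl <- tbl[is.finite(tbl$jsMean) & is.finite(tbl$swcMean), , drop = FALSE]
  if (nrow(tbl) < 10) stop("need >= 10 rows for the SWC regression")
  if (var(tbl$swcMean) == 0) stop("degenerate design: constant SWC")
  fit <- lm(jsMean ~ swcMean, data = tbl)
  sm <- summary(fit)
  list(
    slope = unname(coef(fit)[["swcMean"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r2 = sm$r.squared,
    p = unname(sm$coefficients["swcMean", "Pr(>|t|)"]),
    n = nrow(tbl)
  )
}

#' Logarithmic regression of daily sap flux on VPD
#'
#' OLS of daily mean sap flux density on the natural log of daily mean VPD,
#' \eqn{J_s = a + b \ln(VPD)}, restricted to the tree-days of one moisture
#' label (the wet or dry two-week period). Rows with non-positive VPD are
#' excluded (count in attribute `nExcluded`).
#'
#' @param tbl analysis-table subset (needs `jsMean`, `vpdMean`, `label`).
#' @param label `"wet"` or `"dry"`; `NULL` uses all rows as given.
#' @return list: `a` (intercept), `b` (log-VPD slope), `r2`, `p`, `n`,
#'   `nExcluded`.
#' @export
regressFluxOnVPD <- function(tbl, label = NULL) {
  if (!is.null(label)) tbl <- tbl[tbl$label == label, , drop = FALSE]
  ok <- is.finite(tbl$jsMean) & is.finite(tbl$vpdMean)
  nExcluded <- sum(ok & tbl$vpdMean <= 0)
  tbl <- tbl[ok & tbl$vpdMean > 0, , drop = FALSE]
  if (nrow(tbl) < 3) stop("too few rows with positive VPD")
  fit <- lm(jsMean ~ log(vpdMean), data = tbl)
  sm <- summary(fit)
  list(
    a = unname(coef(fit)[[1]]), b = unname(coef(fit)[[2]]),
    r2 = sm$r.squared,
    p = unname(sm$coefficients[2, "Pr(>|t|)"]),
    n = nrow(tbl), nExcluded = nExcluded
  )
}

#' Maximum sap flux density summary with ANOVA and Tukey letters
#'
#' Per species x elevation x moisture-label group: the mean and SD over
#' trees of each tree's maximum half-hourly sap flux density within the
#' labelled period, a one-way ANOVA across groups, and Tukey HSD compact
#' letters (groups sharing a letter are not significantly different at
#' `alpha`).
#'
#' @param tbl analysis table (needs `tree`, `species`, `elevation`, `jsMax`,
#'   `label`); rows labelled `"neither"` are ignored.
#' @param alpha significance level for the letters.
#' @return data.frame per group: `species`, `elevation`, `label`, `mean`,
#'   `sd`, `n`, `letters`; attribute `anova` (the `aov` summary) unless only
#'   one group.
#' @export
jsmaxSummary <- function(tbl, alpha = 0.05) {
  tbl <- tbl[tbl$label %in% c("dry", "wet") & is.finite(tbl$jsMax), ,
             drop = FALSE]
  if (!nrow(tbl)) stop("no dry/wet labelled rows")
  perTree <- aggregate(
    jsMax ~ tree + species + elevation + label, data = tbl, FUN = max
  )
  perTree$group <- interaction(perTree$species, perTree$elevation,
                               perTree$label, drop = TRUE, sep = "|")
  out <- aggregate(jsMax ~ species + elevation + label + group,
                   data = perTree,
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  stats <- as.data.frame(out$jsMax)
  out <- data.frame(out[c("species", "elevation", "label", "group")],
                    mean = stats$mean, sd = stats$sd, n = stats$n)
  if (nlevels(perTree$group) < 2 || sum(out$n >= 2) < 2) {
    warning("fewer than two groups with replication: no test performed")
    out$letters <- NA_character_
    return(out[order(out$species, out$elevation, out$label), ])
  }
  if (any(out$n < 2))
    warning("groups with a single observation enter the ANOVA unreplicated")
  fit <- aov(jsMax ~ group, data = perTree)
  tk <- TukeyHSD(fit)$group
  lv <- levels(perTree$group)
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_len(nrow(tk))) {
    a <- pairNames[[i]][1]; b <- pairNames[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  lets <- cldLetters(pmat, alpha)
  out$letters <- lets[as.character(out$group)]
  attr(out, "anova") <- summary(fit)
  out[order(out$species, out$elevation, out$label), ]
}
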