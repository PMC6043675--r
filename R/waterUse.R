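#' Whole-tree daily water use
#'
#' Scales the TDP daily flux sums to the whole tree:
#' \deqn{WU = J_{s,sum} \; [g\,cm^{-2}\,day^{-1}] \times A_{eff}\; [cm^2]
#'   \times 10^{-3}\; kg\,g^{-1}.}
#' Trees without geometry are skipped with a message (count in attribute
#' `nSkipped`).
#'
#' @param daily per-tree daily summaries ([summarizeDaily()] rows, columns
#'   `tree`, `date`, `jsSum`).
#' @param geometry data.frame `tree`, `Aeff` (cm^2), e.g. assembled from
#'   [conductingArea()].
#' @return data.frame: `tree`, `date`, `wu` (kg day-1).
#' @export
wholeTreeWaterUse <- function(daily, geometry) {
  stopifnot(all(c("tree", "date", "jsSum") %in% names(daily)),
            all(c("tree", "Aeff") %in% names(geometry)))
  idx <- match(daily$tree, geometry$tree)
  miss <- unique(daily$tree[is.na(idx)])
  if (length(miss))
    message("skipping trees without geometry: ", paste(miss, collapse = ", "))
  keep <- !is.na(idx)
  out <- data.frame(
    tree = daily$tree[keep], date = daily$date[keep],
    wu = daily$jsSum[keep] * geometry$Aeff[idx[keep]] / 1000
  )
  attr(out, "nSkipped") <- length(miss)
  out
}

#' Select sunny high-soil-moisture days
#'
#' The scaling analysis uses "sunny days at high soil moisture". With no
#' radiation channel, sunny is operationalized as daily maximum VPD above
#' the site median (computed over the wet-period days), and high soil
#' moisture as membership in a wet moisture period.
#'
#' @param drivers daily driver table ([dailyDrivers()]).
#' @param periods moisture periods ([classifyMoisturePeriods()]).
#' @return `Date` vector of qualifying days.
#' @export
sunnyWetDays <- function(drivers, periods) {
  lab <- moistureLabel(drivers$date, periods)
  wet <- drivers[lab == "wet" & drivers$valid, , drop = FALSE]
  if (!nrow(wet)) return(as.Date(character()))
  wet$date[wet$vpdMax >= median(wet$vpdMax, na.rm = TRUE)]
}

#' Water use vs diameter scaling
#'
#' Ordinary least squares of per-tree mean daily water use on DBH across
#' species — the classical tree-size scaling relation, evaluated under
#' favorable conditions. The per-tree mean over qualifying days (not pooled
#' tree-days) enters the regression.
#'
#' @param wu water-use records ([wholeTreeWaterUse()]).
#' @param meta tree metadata with columns `tree`, `dbh`.
#' @param days optional `Date` vector restricting which days enter the
#'   per-tree means (e.g. [sunnyWetDays()]); `NULL` uses all days.
#' @return list: `slope` (kg day-1 cm-1), `intercept`, `r2`, `p`, `n`
#'   (trees), `perTree` (the tree means entering the fit).
#' @export
fitDbhScaling <- function(wu, meta, days = NULL) {
  if (!is.null(days)) wu <- wu[wu$date %in% days, , drop = FALSE]
  mt <- aggregate(wu ~ tree, data = wu, FUN = mean, na.rm = TRUE)
  mt$dbh <- meta$dbh[match(mt$tree, meta$tree)]
  mt <- mt[is.finite(mt$wu) & is.finite(mt$dbh), , drop = FALSE]
  if (nrow(mt) < 3) stop("need >= 3 trees for the scaling fit")
  if (var(mt$dbh) == 0) stop("degenerate design: all DBH identical")
  if (var(mt$wu) == 0) {
    return(list(slope = 0, intercept = mt$wu[1], r2 = 0, p = NA_real_,
                n = nrow(mt), perTree = mt))
  }
  fit <- lm(wu ~ dbh, data = mt)
  sm <- summary(fit)
  p <- if (!is.null(sm$fstatistic))
    pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
       sm$fstatistic[["dendf"]], lower.tail = FALSE) else NA_real_
  list(
    slope = unname(coef(fit)[["dbh"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r2 = sm$r.squared, p = unname(p), n = nrow(mt), perTree = mt
  )
}
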