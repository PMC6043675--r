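#' @import methods
NULL

VALID_CHANNELS <- c("T", "RH", "SWC", "VPD", "dT", "Js")

CHANNEL_UNITS <- c(
  T = "degC", RH = "%", SWC = "%vol", VPD = "hPa",
  dT = "K", Js = "g cm-2 h-1"
)

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Half-hourly sensor or derived series
#'
#' The basic time-series container of the package: one logger channel on a
#' strict 30-minute grid. Gaps are explicit `NA` values, never missing
#' timestamps, so alignment between channels is positional. Channel-specific
#' range invariants (relative humidity and volumetric soil water content in
#' \eqn{[0, 100]}, vapor pressure deficit and sap flux density non-negative,
#' TDP temperature differentials strictly positive) are enforced by the
#' validity method.
#'
#' @slot time `POSIXct` timestamps (UTC), strictly increasing, 30-min spacing.
#' @slot values numeric channel values; `NA` marks a logger gap.
#' @slot channel one of `"T"`, `"RH"`, `"SWC"`, `"VPD"`, `"dT"`, `"Js"`.
#' @slot units unit string, filled from the channel by [halfHourlySeries()].
#' @slot site site/elevation label, or `NULL`.
#' @slot tree tree identifier for per-tree channels, or `NULL`.
#' @slot azimuth sensor azimuth (`"north"`/`"south"`) for TDP channels.
#'
#' @seealso [halfHourlySeries()], [seriesValues()], [seriesTimes()]
#' @export
setClass("HalfHourlySeries",
  representation(
    time = "POSIXct", values = "numeric", channel = "character",
    units = "character", site = "characterOrNULL", tree = "characterOrNULL",
    azimuth = "characterOrNULL"
  )
)

setValidity("HalfHourlySeries", function(object) {
  msg <- character()
  if (length(object@time) != length(object@values))
    msg <- c(msg, "time and values must have equal length")
  if (!isHalfHourly(object@time))
    msg <- c(msg, "timestamps must be strictly increasing with 30-min spacing")
  if (!(object@channel %in% VALID_CHANNELS))
    msg <- c(msg, paste0("unknown channel '", object@channel, "'"))
  v <- object@values[!is.na(object@values)]
  if (object@channel %in% c("RH", "SWC") && length(v) && any(v < 0 | v > 100))
    msg <- c(msg, paste0(object@channel, " values must lie in [0, 100]"))
  if (object@channel %in% c("VPD", "Js") && length(v) && any(v < 0))
    msg <- c(msg, paste0(object@channel, " values must be >= 0"))
  if (object@channel == "dT" && length(v) && any(v <= 0))
    msg <- c(msg, "dT values must be > 0 wherever valid")
  if (length(msg)) msg else TRUE
})

#' Construct a half-hourly series
#'
#' @param time `POSIXct` timestamps on the 30-min grid.
#' @param values numeric values (`NA` = gap).
#' @param channel channel label; determines units and validity rules.
#' @param site,tree,azimuth optional provenance labels.
#' @return a [HalfHourlySeries-class] object.
#' @examples
#' tm <- halfHourlyGrid("2015-01-01", "2015-01-01")
#' swc <- halfHourlySeries(tm, rep(20, 48), "SWC", site = "860")
#' @export
halfHourlySeries <- function(time, values, channel,
                             site = NULL, tree = NULL, azimuth = NULL) {
  new("HalfHourlySeries",
    time = time, values = as.numeric(values), channel = channel,
    units = unname(CHANNEL_UNITS[channel]), site = site, tree = tree,
    azimuth = azimuth
  )
}

setMethod("show", "HalfHourlySeries", function(object) {
  n <- length(object@values)
  cat(sprintf(
    "HalfHourlySeries <%s> [%s], %d records (%d NA)\n",
    object@channel, object@units, n, sum(is.na(object@values))
  ))
  if (n) cat(sprintf(
    "  %s .. %s%s%s\n",
    format(object@time[1]), format(object@time[n]),
    if (!is.null(object@site)) paste0("  site=", object@site) else "",
    if (!is.null(object@tree)) paste0("  tree=", object@tree) else ""
  ))
})

#' Gaussian radial flux profile fit
#'
#' Parameters of the Gaussian flux-depth shape
#' \eqn{f(d) = A \exp(-(d-\mu)^2 / (2\sigma^2))} fitted to a normalized HFD
#' radial profile, together with convergence/degeneracy diagnostics and
#' provenance (was the profile substituted from another species?).
#'
#' @slot tree,species identifiers (may be `NA`).
#' @slot A amplitude of the normalized profile (dimensionless).
#' @slot mu centre depth beneath the cambium (cm).
#' @slot sigma width (cm).
#' @slot r2 goodness of fit of the nonlinear least squares.
#' @slot converged did the optimizer converge.
#' @slot degenerate `TRUE` when a parameter sits on its bound
#'   (unidentifiable shape, e.g. a constant profile).
#' @slot substituted `TRUE` when the fit was borrowed from another species.
#' @export
setClass("GaussianProfileFit",
  representation(
    tree = "character", species = "character",
    A = "numeric", mu = "numeric", sigma = "numeric", r2 = "numeric",
    converged = "logical", degenerate = "logical", substituted = "logical"
  ),
  prototype(
    tree = NA_character_, species = NA_character_, r2 = NA_real_,
    converged = TRUE, degenerate = FALSE, substituted = FALSE
  )
)

setValidity("GaussianProfileFit", function(object) {
  msg <- character()
  if (object@converged && !object@degenerate) {
    if (!is.na(object@A) && object@A <= 0) msg <- c(msg, "A must be > 0")
    if (!is.na(object@sigma) && object@sigma <= 0)
      msg <- c(msg, "sigma must be > 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaussianProfileFit", function(object) {
  cat(sprintf(
    "GaussianProfileFit%s%s: A=%.4g mu=%.4g cm sigma=%.4g cm R2=%.3f%s%s\n",
    if (!is.na(object@tree)) paste0(" tree=", object@tree) else "",
    if (!is.na(object@species)) paste0(" [", object@species, "]") else "",
    object@A, object@mu, object@sigma, object@r2,
    if (object@degenerate) " (degenerate)" else "",
    if (object@substituted) " (substituted)" else ""
  ))
})

#' Diurnal sap flux / VPD hysteresis loop
#'
#' One day's trajectory in the (VPD, Js) plane at hourly (default) or
#' half-hourly resolution, with shoelace signed area, rotation direction and
#' peak times. Clockwise rotation (negative signed area with x = VPD,
#' y = Js) means sap flux peaks before atmospheric demand.
#'
#' @slot date the day.
#' @slot group grouping label (typically species x elevation).
#' @slot hour fractional hours of the vertices, in time order.
#' @slot vpd,js vertex coordinates (hPa; g cm-2 h-1).
#' @slot signedArea shoelace area of the closed polygon ((g cm-2 h-1) hPa).
#' @slot rotation `"clockwise"`, `"counterclockwise"` or `"degenerate"`.
#' @slot jsPeak,vpdPeak fractional hour of the Js and VPD maxima.
#' @slot selfIntersecting polygon edge-crossing flag (area still reported).
#' @export
setClass("HysteresisLoop",
  representation(
    date = "Date", group = "character", hour = "numeric",
    vpd = "numeric", js = "numeric", signedArea = "numeric",
    rotation = "character", jsPeak = "numeric", vpdPeak = "numeric",
    selfIntersecting = "logical"
  )
)

setValidity("HysteresisLoop", function(object) {
  msg <- character()
  n <- length(object@hour)
  if (length(object@vpd) != n || length(object@js) != n)
    msg <- c(msg, "hour, vpd and js must have equal length")
  if (n < 12) msg <- c(msg, "a loop needs at least 12 vertices")
  if (!(object@rotation %in% c("clockwise", "counterclockwise", "degenerate")))
    msg <- c(msg, "invalid rotation label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HysteresisLoop", function(object) {
  cat(sprintf(
    "HysteresisLoop %s [%s]: area=%.3f (%s), Js peak %05.2fh, VPD peak %05.2fh%s\n",
    format(object@date), object@group, object@signedArea, object@rotation,
    object@jsPeak, object@vpdPeak,
    if (object@selfIntersecting) " (self-intersecting)" else ""
  ))
})

#' Mixed-model analysis result
#'
#' Wraps an `lme4` random-intercept fit of daily sap flux on its
#' environmental and structural drivers together with the quantities the
#' analysis reports: a Satterthwaite-denominator-df ANOVA table, variance
#' components, and marginal/conditional R-squared (variance explained by the
#' fixed effects alone vs fixed plus the per-tree random intercept).
#'
#' @slot fit the underlying `lmerMod`.
#' @slot anova data.frame with `Sum Sq`, `Mean Sq`, `NumDF`, `DenDF`,
#'   `F value`, `Pr(>F)` per fixed term.
#' @slot varcomp named numeric: `tree` and `residual` variances.
#' @slot r2m,r2c marginal and conditional R-squared.
#' @slot singular `TRUE` when the random-effect variance collapsed to zero.
#' @slot centering named list of the covariate means subtracted before
#'   forming interactions (empty when centring was off).
#' @slot data the analysis table the model was fitted to.
#' @export
setClass("MixedModelResult",
  representation(
    fit = "ANY", anova = "data.frame", varcomp = "numeric",
    r2m = "numeric", r2c = "numeric", singular = "logical",
    centering = "list", data = "data.frame"
  )
)

setValidity("MixedModelResult", function(object) {
  msg <- character()
  if (any(object@varcomp < 0)) msg <- c(msg, "variance components must be >= 0")
  if (!is.na(object@r2m) && !is.na(object@r2c) &&
      object@r2c < object@r2m - 1e-8)
    msg <- c(msg, "conditional R2 must be >= marginal R2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixedModelResult", function(object) {
  cat("MixedModelResult (random intercept per tree)\n")
  cat(sprintf(
    "  varcomp: tree=%.4g residual=%.4g%s\n",
    object@varcomp[["tree"]], object@varcomp[["residual"]],
    if (object@singular) " [singular]" else ""
  ))
  cat(sprintf("  R2 marginal=%.3f conditional=%.3f\n", object@r2m, object@r2c))
  print(object@anova, digits = 4)
})

#' A generated synthetic sap-flow study
#'
#' Container for one realization of the synthetic study design: tree
#' metadata, per-site half-hourly microclimate, inverted TDP sensor signals,
#' HFD radial observations, and the full ground truth (true sap flux series,
#' true zero-flow baselines, true profile parameters) needed to verify every
#' pipeline stage.
#'
#' @slot config the generator configuration (see [studyConfig()]).
#' @slot seed integer seed the realization was drawn with.
#' @slot trees per-tree metadata data.frame.
#' @slot climate long data.frame: `time`, `site`, `T`, `RH`, `SWC`, `VPD`.
#' @slot sensors long data.frame: `time`, `tree`, `azimuth`, `dT`.
#' @slot profiles HFD radial observations: `tree`, `species`, `depth`, `value`.
#' @slot truth list with elements `flux` (long `time`/`tree`/`js`), `dTmax`
#'   (per tree x azimuth), `profiles` (true A/mu/sigma per species) and
#'   `speciesParams`.
#' @export
setClass("SyntheticStudy",
  representation(
    config = "list", seed = "integer", trees = "data.frame",
    climate = "data.frame", sensors = "data.frame", profiles = "data.frame",
    truth = "list"
  )
)

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf(
    "SyntheticStudy: %d trees, %d sites, %s .. %s (seed %d)\n",
    nrow(object@trees), length(unique(object@trees$elevation)),
    object@config$dates$from, object@config$dates$to, object@seed
  ))
})
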