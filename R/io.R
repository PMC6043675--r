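parseTime <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                            "%Y-%m-%d %H:%M:%S"))
}

#' Read a long-format climate CSV
#'
#' Long delimited text with columns `timestamp` (ISO-8601), `site`,
#' `channel` (`T`/`RH`/`SWC`), `value`, as written by
#' [writeFixtureDataset()] or produced from logger exports.
#' An optional alias map substitutes one site's channel with another's
#' (e.g. adopting mid-elevation humidity for a site whose hygrometer
#' failed).
#'
#' @param path CSV path.
#' @param alias named list mapping `"site.channel"` to the donor
#'   `"site.channel"`, e.g. `list("670.RH" = "860.RH")`.
#' @return named list (per site) of named lists (per channel) of
#'   [HalfHourlySeries-class].
#' @export
readClimateCSV <- function(path, alias = NULL) {
  raw <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("timestamp", "site", "channel", "value") %in% names(raw)))
  raw$time <- parseTime(raw$timestamp)
  out <- list()
  for (site in unique(raw$site)) {
    chans <- list()
    sub <- raw[raw$site == site, ]
    for (ch in unique(sub$channel)) {
      s <- sub[sub$channel == ch, ]
      s <- s[order(s$time), ]
      chans[[ch]] <- halfHourlySeries(s$time, s$value, ch,
                                      site = as.character(site))
    }
    out[[as.character(site)]] <- chans
  }
  for (dst in names(alias)) {
    d <- strsplit(dst, ".", fixed = TRUE)[[1]]
    s <- strsplit(alias[[dst]], ".", fixed = TRUE)[[1]]
    src <- out[[s[1]]][[s[2]]]
    out[[d[1]]][[d[2]]] <- halfHourlySeries(src@time, src@values, s[2],
                                            site = d[1])
  }
  out
}

#' Read a TDP sensor CSV
#'
#' Columns `timestamp`, `tree`, `azimuth`, `dT`.
#'
#' @param path CSV path.
#' @return named list (per tree) of named lists (per azimuth) of `"dT"`
#'   [HalfHourlySeries-class].
#' @export
readSensorCSV <- function(path) {
  raw <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("timestamp", "tree", "azimuth", "dT") %in% names(raw)))
  raw$time <- parseTime(raw$timestamp)
  out <- list()
  for (tr in unique(raw$tree)) {
    sub <- raw[raw$tree == tr, ]
    az <- list()
    for (a in unique(sub$azimuth)) {
      s <- sub[sub$azimuth == a, ]
      s <- s[order(s$time), ]
      az[[a]] <- halfHourlySeries(s$time, s$dT, "dT", tree = tr, azimuth = a)
    }
    out[[tr]] <- az
  }
  out
}
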