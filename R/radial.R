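## Default HFD depth convention: eight 1-cm bins, midpoints beneath cambium.
HFD_DEPTHS <- seq(0.5, 7.5, by = 1)

#' Normalize a radial flux profile to the TDP reference
#'
#' HFD profiles are expressed relative to the flux the TDP probe itself
#' sees, so that multiplying the conducting area by TDP flux gives
#' whole-tree flow. The default reference is the mean over the outer 0--2 cm
#' (the 20-mm TDP probe span); `"point1cm"` uses the value interpolated at
#' 1 cm depth instead.
#'
#' @param depths depths beneath cambium, cm, strictly increasing.
#' @param values mean daily flux at each depth (>= 0).
#' @param reference `"span02"` (default) or `"point1cm"`.
#' @param tree identifier used in error messages.
#' @return list: `depths`, `values` (dimensionless, reference value 1),
#'   `reference`, `refValue` (the divisor, original units).
#' @export
normalizeProfile <- function(depths, values,
                             reference = c("span02", "point1cm"),
                             tree = "?") {
  reference <- match.arg(reference)
  stopifnot(length(depths) == length(values), !is.unsorted(depths, strictly = TRUE))
  ref <- switch(reference,
    span02 = mean(values[depths <= 2], na.rm = TRUE),
    point1cm = stats::approx(depths, values, xout = 1, rule = 2)$y
  )
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("non-positive normalization reference for tree %s", tree))
  list(depths = depths, values = values / ref, reference = reference,
       refValue = ref)
}

#' Fit a Gaussian to a normalized radial profile
#'
#' Nonlinear least squares of \eqn{f(d) = A \exp(-(d-\mu)^2/(2\sigma^2))}
#' against the normalized per-depth values, the shape that best describes
#' radial variation of sap flux with xylem depth. Initialized at the profile
#' maximum with \eqn{\sigma = 2} cm; box bounds keep the centre within 2 cm
#' of the sampled span and the width in (0.1, 20] cm. A width ending on its
#' upper bound (flat, unidentifiable profile) or a failed optimizer is
#' flagged, so callers can fall back to a species-mean profile.
#'
#' @param depths,values normalized profile (>= 4 valid depths).
#' @param tree,species identifiers carried into the result.
#' @return a [GaussianProfileFit-class] object.
#' @export
fitGaussianProfile <- function(depths, values, tree = NA_character_,
                               species = NA_character_) {
  ok <- is.finite(depths) & is.finite(values)
  depths <- depths[ok]; values <- values[ok]
  if (length(depths) < 4) stop("need >= 4 valid depths to fit a profile")
  lower <- c(A = 1e-6, mu = -2, sigma = 0.1)
  upper <- c(A = 10, mu = max(depths) + 2, sigma = 20)
  start <- c(A = max(values), mu = depths[which.max(values)], sigma = 2)
  start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
  dat <- data.frame(d = depths, y = values)
  fit <- tryCatch(
    nls(y ~ A * exp(-(d - mu)^2 / (2 * sigma^2)), data = dat,
        start = as.list(start), lower = lower, upper = upper,
        algorithm = "port",
        control = list(warnOnly = FALSE, maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new("GaussianProfileFit", tree = tree, species = species,
               A = NA_real_, mu = NA_real_, sigma = NA_real_, r2 = NA_real_,
               converged = FALSE, degenerate = TRUE))
  }
  p <- coef(fit)
  ssRes <- sum(resid(fit)^2)
  ssTot <- sum((values - mean(values))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  atBound <- function(name) {
    p[[name]] <= lower[[name]] + 1e-6 || p[[name]] >= upper[[name]] - 1e-6
  }
  degenerate <- atBound("sigma") || atBound("A") || atBound("mu") ||
    !is.finite(r2)
  new("GaussianProfileFit", tree = tree, species = species,
      A = unname(p[["A"]]), mu = unname(p[["mu"]]),
      sigma = unname(p[["sigma"]]), r2 = r2,
      converged = TRUE, degenerate = degenerate)
}

profileFunction <- function(fit) {
  p <- profileParams(fit)
  function(d) p[["A"]] * exp(-(d - p[["mu"]])^2 / (2 * p[["sigma"]]^2))
}

#' Effective conducting sapwood area by solid of revolution
#'
#' Rotates the normalized radial profile around the stem axis:
#' \deqn{A_{eff} = \int_0^D f(d)\, 2\pi (R - d)\, dd}
#' with \eqn{R} the under-bark stem radius and \eqn{D} the integration depth
#' limit. Because \eqn{f} is normalized to the TDP reference, multiplying
#' \eqn{A_{eff}} by the TDP flux density gives whole-tree flow. Evaluated by
#' adaptive quadrature (`stats::integrate`, rel.tol 1e-8).
#'
#' @param fit a [GaussianProfileFit-class], or a function of depth.
#' @param R under-bark stem radius, cm.
#' @param D integration depth limit, cm, `0 < D <= R`.
#' @return effective conducting area, cm^2.
#' @seealso [annulusSumArea()] for the brute-force cross-check.
#' @export
conductingArea <- function(fit, R, D) {
  stopifnot(D > 0, R > 0)
  if (D > R) stop("integration depth D exceeds stem radius R")
  f <- if (is.function(fit)) fit else profileFunction(fit)
  g <- function(d) {
    y <- f(d) * 2 * pi * (R - d)
    stopifnot(all(y >= -1e-12))
    y
  }
  ## split at the profile maximum (and, for Gaussian fits, at mu +/- 1 and
  ## 4 sigma): a narrow peak or steep tail can otherwise slip between the
  ## quadrature nodes
  knots <- if (is(fit, "GaussianProfileFit")) {
    fit@mu + c(-4, -1, 0, 1, 4) * fit@sigma
  } else {
    stats::optimize(f, c(0, D), maximum = TRUE)$maximum
  }
  knots <- pmin(pmax(knots, 0), D)
  pieces <- sort(unique(c(0, knots, D)))
  sum(vapply(seq_len(length(pieces) - 1), function(i)
    integrate(g, pieces[i], pieces[i + 1], rel.tol = 1e-8,
              abs.tol = 0)$value, numeric(1)))
}

#' Brute-force annulus-sum conducting area
#'
#' Independent check of [conductingArea()]: sums thin annuli of width
#' `step`, \eqn{\sum_i f(d_i)\, 2\pi (R - d_i)\, \Delta d} at bin midpoints.
#'
#' @inheritParams conductingArea
#' @param step annulus width, cm (default 1e-3).
#' @return effective conducting area, cm^2.
#' @export
annulusSumArea <- function(fit, R, D, step = 1e-3) {
  stopifnot(D > 0, D <= R)
  f <- if (is.function(fit)) fit else profileFunction(fit)
  nFull <- floor(D / step)
  mids <- (seq_len(nFull) - 0.5) * step
  total <- sum(f(mids) * 2 * pi * (R - mids)) * step
  rem <- D - nFull * step  # partial last annulus
  if (rem > 0) {
    m <- nFull * step + rem / 2
    total <- total + f(m) * 2 * pi * (R - m) * rem
  }
  total
}

#' Substitute a species' radial profile from another species
#'
#' When HFD measurement fails for a species, its trees adopt the mean
#' fitted parameters of a donor species as a simple approximation. The
#' donor mean is taken over its converged, non-degenerate fits, averaging
#' fitted parameters (not raw profiles — robust to missing depths).
#'
#' @param targetSpecies species to receive the profile.
#' @param sourceSpecies donor species.
#' @param fits list of [GaussianProfileFit-class] objects (the profile
#'   library across trees/species).
#' @return a [GaussianProfileFit-class] with `substituted = TRUE` and the
#'   donor parameter means (`r2` is the donor mean R2).
#' @export
substituteProfile <- function(targetSpecies, sourceSpecies, fits) {
  sp <- vapply(fits, function(f) f@species, character(1))
  usable <- vapply(fits, function(f) f@converged && !f@degenerate, logical(1))
  src <- fits[sp == sourceSpecies & usable]
  if (!length(src)) {
    stop(sprintf(
      "no usable fits for source species '%s'; available: %s",
      sourceSpecies, paste(sort(unique(sp[usable])), collapse = ", ")
    ))
  }
  pm <- rowMeans(vapply(src, profileParams, numeric(3)))
  new("GaussianProfileFit", tree = NA_character_, species = targetSpecies,
      A = pm[["A"]], mu = pm[["mu"]], sigma = pm[["sigma"]],
      r2 = mean(vapply(src, function(f) f@r2, numeric(1))),
      converged = TRUE, degenerate = FALSE,
      substituted = !identical(targetSpecies, sourceSpecies))
}

#' Stem geometry from diameter
#'
#' Under-bark radius and integration depth from DBH: `R = DBH/2 -
#' barkAllowance`, `D = min(maxDepth, R)`. The depth cap defaults to the
#' 8-cm HFD sensing span.
#'
#' @param dbh diameter at breast height, cm.
#' @param barkAllowance radial bark thickness subtracted, cm.
#' @param maxDepth integration depth cap, cm.
#' @return data.frame: `R`, `D`.
#' @export
stemGeometry <- function(dbh, barkAllowance = 1, maxDepth = 8) {
  R <- dbh / 2 - barkAllowance
  stopifnot(all(R > 0))
  data.frame(R = R, D = pmin(maxDepth, R))
}
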