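## Fixed-effect structure of the daily sap-flux model: SWC, VPD, species,
## elevation as fixed factors, DBH as covariate, exactly six two-way
## interactions, random intercept per tree.
FIXED_TERMS <- c(
  "SWC", "VPD", "species", "elevation", "DBH",
  "SWC:species", "SWC:elevation", "species:elevation",
  "VPD:species", "VPD:elevation", "SWC:VPD"
)

fixedFormula <- function(response = "Js") {
  as.formula(paste(response, "~", paste(FIXED_TERMS, collapse = " + ")))
}

## Shared design construction: rename to model variables, centre covariates,
## sum-to-zero contrasts for the factors (so selecting a term's coefficient
## block yields type-III style marginal tests).
mixedDesign <- function(tbl, center = TRUE, response = "jsMean") {
  d <- data.frame(
    Js = tbl[[response]],
    SWC = tbl$swcMean, VPD = tbl$vpdMean,
    species = factor(tbl$species),
    elevation = factor(tbl$elevation),
    DBH = tbl$dbh, tree = factor(tbl$tree)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  centering <- list()
  if (center) {
    for (v in c("SWC", "VPD", "DBH")) {
      centering[[v]] <- mean(d[[v]])
      d[[v]] <- d[[v]] - centering[[v]]
    }
  }
  stats::contrasts(d$species) <- contr.sum(nlevels(d$species))
  stats::contrasts(d$elevation) <- contr.sum(nlevels(d$elevation))
  list(data = d, centering = centering)
}

#' Fit the daily sap-flux mixed model
#'
#' Linear mixed model of daily sap flux density on soil water content, VPD,
#' species, elevation (fixed), DBH (covariate) with the six two-way
#' interactions SWC:VPD, SWC:species, SWC:elevation, VPD:species,
#' VPD:elevation and species:elevation, and a random intercept per tree
#' (REML, `lme4`). Covariates are mean-centred before interactions are
#' formed (reduces collinearity; reversible via the stored means) and
#' factors use sum-to-zero contrasts. The ANOVA table uses Satterthwaite
#' denominator degrees of freedom; marginal and conditional R-squared follow
#' the variance-partition formulation
#' \eqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{tree} + \sigma^2_e)},
#' \eqn{R^2_c = (\sigma^2_f + \sigma^2_{tree}) / (\cdot)} with
#' \eqn{\sigma^2_f} the variance of the fixed-effect predictor.
#'
#' An empty species x elevation cell (the study design has no evergreen
#' trees at the top site) makes the species:elevation block rank deficient;
#' the affected columns are dropped and the term's numerator df shrinks
#' accordingly.
#'
#' @param tbl analysis table ([buildAnalysisTable()] columns: `tree`,
#'   `species`, `elevation`, `dbh`, `swcMean`, `vpdMean`, and the response).
#' @param response column used as response: `"jsMean"` (default) or
#'   `"jsSum"`.
#' @param center centre SWC, VPD, DBH before forming interactions.
#' @return a [MixedModelResult-class] object.
#' @export
fitMixedModel <- function(tbl, response = "jsMean", center = TRUE) {
  des <- mixedDesign(tbl, center = center, response = response)
  d <- des$data
  if (min(table(d$tree)) < 2)
    warning("some trees have < 2 observations; random intercept weakly identified")
  form <- stats::update(fixedFormula(), . ~ . + (1 | tree))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      check.rankX = "silent.drop.cols"))
  singular <- lme4::isSingular(fit)
  vc <- lme4::VarCorr(fit)
  s2tree <- as.numeric(vc$tree[1, 1])
  s2res <- stats::sigma(fit)^2
  s2fix <- var(as.vector(getMEX(fit) %*% lme4::fixef(fit)))
  denom <- s2fix + s2tree + s2res
  r2m <- if (denom > 0) s2fix / denom else NA_real_
  r2c <- if (denom > 0) (s2fix + s2tree) / denom else NA_real_
  av <- satterthwaiteAnova(fit)
  new("MixedModelResult",
    fit = fit, anova = av, varcomp = c(tree = s2tree, residual = s2res),
    r2m = r2m, r2c = r2c, singular = singular,
    centering = des$centering, data = d
  )
}

getMEX <- function(fit) lme4::getME(fit, "X")

## --- Satterthwaite machinery (random-intercept models) -------------------
##
## Asymptotic covariance of the variance parameters comes from the Hessian
## of the unprofiled REML deviance in (theta, sigma); the covariance of the
## fixed effects as a function of those parameters uses the Woodbury
## identity, cheap because the random structure is a single scalar
## intercept: Sigma = I + theta^2 Z Z'  =>
## X' Sigma^-1 X = X'X - theta^2 (X'Z) (I + theta^2 Z'Z)^-1 (Z'X).

satterthwaitePrep <- function(fit) {
  stopifnot(length(lme4::getME(fit, "theta")) == 1L)
  X <- getMEX(fit)
  Z <- lme4::getME(fit, "Z")
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(Matrix::Matrix(X), Z))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  q <- ncol(Z)
  vcovBeta <- function(varpar) {
    th <- varpar[1]; s2 <- varpar[2]^2
    M <- diag(q) + th^2 * ZtZ
    XtSiX <- XtX - th^2 * XtZ %*% solve(M, t(XtZ))
    s2 * solve(XtSiX)
  }
  ## unprofiled REML deviance as a function of (theta, sigma)
  devfun <- lme4::lmer(formula(fit), data = stats::model.frame(fit),
                       REML = TRUE, devFunOnly = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         check.rankX = "silent.drop.cols"))
  rho <- environment(devfun)
  n <- length(rho$resp$y); p <- ncol(rho$pp$X)
  devfunVP <- function(varpar) {
    th <- varpar[1]; s2 <- varpar[2]^2
    devfun(th)
    prss <- rho$resp$wrss() + rho$pp$sqrL(1)
    rho$pp$ldL2() + rho$pp$ldRX2() + (n - p) * log(2 * pi * s2) + prss / s2
  }
  est <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  H <- numDeriv::hessian(devfunVP, est)
  W <- tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, 2, 2))
  list(vcovBeta = vcovBeta, est = est, W = W, beta = lme4::fixef(fit),
       V = vcovBeta(est), s2res = stats::sigma(fit)^2)
}

## Satterthwaite df for a single contrast row l: f(vp) = l' A(vp) l,
## df = 2 f^2 / (g' W g) with g the gradient of f at the estimates.
satterthwaiteDfRow <- function(l, prep, h = 1e-5) {
  fFun <- function(vp) as.numeric(t(l) %*% prep$vcovBeta(vp) %*% l)
  g <- vapply(1:2, function(i) {
    hi <- h * max(abs(prep$est[i]), 1)
    e <- numeric(2); e[i] <- hi
    (fFun(prep$est + e) - fFun(prep$est - e)) / (2 * hi)
  }, numeric(1))
  f0 <- fFun(prep$est)
  den <- as.numeric(t(g) %*% prep$W %*% g)
  if (!is.finite(den) || den <= 0) return(Inf)
  2 * f0^2 / den
}

## Multi-df F test with Satterthwaite denominator df by eigendecomposition
## of the contrast covariance (Fai-Cornelius style).
satterthwaiteFTest <- function(L, prep) {
  qd <- nrow(L)
  Lb <- L %*% prep$beta
  VL <- L %*% prep$V %*% t(L)
  Fval <- as.numeric(t(Lb) %*% solve(VL, Lb)) / qd
  ee <- eigen(VL, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-10
  nus <- vapply(which(pos), function(i) {
    u <- as.numeric(t(ee$vectors[, i]) %*% L)
    satterthwaiteDfRow(u, prep)
  }, numeric(1))
  nus <- nus[is.finite(nus) & nus > 2]
  if (!length(nus)) {
    ddf <- NA_real_
  } else {
    E <- sum(nus / (nus - 2))
    ddf <- if (E > qd) 2 * E / (E - qd) else NA_real_
  }
  p <- if (is.na(ddf)) NA_real_ else pf(Fval, qd, ddf, lower.tail = FALSE)
  c(NumDF = qd, DenDF = ddf, F = Fval, p = p)
}

#' Satterthwaite ANOVA table for a random-intercept fit
#'
#' Marginal (type-III style, valid under the package's sum-to-zero coding)
#' F tests of every fixed term, with Satterthwaite denominator degrees of
#' freedom. `Sum Sq` is reconstructed as `F x NumDF x` residual variance,
#' matching the convention of mixed-model ANOVA tables.
#'
#' @param fit an `lmerMod` with one scalar random intercept.
#' @return data.frame rows per term: `Sum Sq`, `Mean Sq`, `NumDF`, `DenDF`,
#'   `F value`, `Pr(>F)`.
#' @export
satterthwaiteAnova <- function(fit) {
  prep <- satterthwaitePrep(fit)
  X <- getMEX(fit)
  asgn <- attr(X, "assign")
  if (is.null(asgn))
    stop("model matrix lacks term assignment")
  labels <- attr(terms(fit), "term.labels")
  p <- length(prep$beta)
  rows <- lapply(seq_along(labels), function(ti) {
    cols <- which(asgn == ti)
    if (!length(cols)) return(NULL)
    L <- matrix(0, length(cols), p)
    L[cbind(seq_along(cols), cols)] <- 1
    satterthwaiteFTest(L, prep)
  })
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[keep])
  data.frame(
    `Sum Sq` = m[, "F"] * m[, "NumDF"] * prep$s2res,
    `Mean Sq` = m[, "F"] * prep$s2res,
    NumDF = m[, "NumDF"], DenDF = m[, "DenDF"],
    `F value` = m[, "F"], `Pr(>F)` = m[, "p"],
    row.names = labels[keep], check.names = FALSE
  )
}

#' Fixed-effect coefficient table with Satterthwaite df
#'
#' Estimates, standard errors, Satterthwaite degrees of freedom, t and p
#' values and 95 % confidence intervals for every fixed-effect coefficient
#' of a fitted [MixedModelResult-class].
#'
#' @param result a [MixedModelResult-class].
#' @return data.frame rows per coefficient: `estimate`, `se`, `df`, `t`,
#'   `p`, `lower`, `upper`.
#' @export
coefTable <- function(result) {
  fit <- result@fit
  prep <- satterthwaitePrep(fit)
  p <- length(prep$beta)
  out <- do.call(rbind, lapply(seq_len(p), function(i) {
    l <- numeric(p); l[i] <- 1
    se <- sqrt(prep$V[i, i])
    df <- satterthwaiteDfRow(l, prep)
    tv <- prep$beta[i] / se
    data.frame(
      estimate = prep$beta[i], se = se, df = df, t = tv,
      p = 2 * pt(abs(tv), df, lower.tail = FALSE),
      lower = prep$beta[i] - qt(0.975, df) * se,
      upper = prep$beta[i] + qt(0.975, df) * se
    )
  }))
  rownames(out) <- names(prep$beta)
  out
}

## --- compact letter display ----------------------------------------------

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-absorb algorithm: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p-values (diagonal ignored),
#'   dimnames = group labels.
#' @param alpha significance level.
#' @return named character vector of letter strings.
#' @export
cldLetters <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  labs <- rownames(pmat) %||% as.character(seq_len(k))
  sets <- list(seq_len(k))
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  pairs <- pairs[!is.na(pmat[pairs]) & pmat[pairs] < alpha, , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    nxt <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
      } else nxt <- c(nxt, list(s))
    }
    nxt <- nxt[lengths(nxt) > 0]
    drop <- rep(FALSE, length(nxt))
    for (a in seq_along(nxt)) {
      for (b in seq_along(nxt)) {
        if (a == b || drop[a] || drop[b]) next
        if (all(nxt[[a]] %in% nxt[[b]]) &&
            (length(nxt[[a]]) < length(nxt[[b]]) || a > b))
          drop[a] <- TRUE
      }
    }
    sets <- nxt[!drop]
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  names(out) <- labs
  out
}

## --- least-squares means --------------------------------------------------

lsCellRow <- function(result, species, elevation, delta = list()) {
  d <- result@data
  nd <- data.frame(
    SWC = mean(d$SWC) + (delta$SWC %||% 0),
    VPD = mean(d$VPD) + (delta$VPD %||% 0),
    DBH = mean(d$DBH),
    species = factor(species, levels = levels(d$species)),
    elevation = factor(elevation, levels = levels(d$elevation))
  )
  stats::contrasts(nd$species) <- stats::contrasts(d$species)
  stats::contrasts(nd$elevation) <- stats::contrasts(d$elevation)
  mm <- model.matrix(fixedFormula()[-2], nd)
  mm[1, colnames(getMEX(result@fit)), drop = TRUE]
}

#' Least-squares means and driver sensitivities per species x elevation
#'
#' Model-implied adjusted means (`focus = "mean"`) or marginal driver
#' slopes (`focus = "SWC"` or `"VPD"`, the sap-flux sensitivity to that
#' driver) for every species x elevation cell, at reference values of the
#' remaining covariates (sample means). Cells absent from the data (the
#' evergreen species is missing at the top elevation) are reported with
#' `present = FALSE` and no estimate rather than extrapolated. Pairwise
#' comparisons among present cells are Tukey-adjusted (studentized range)
#' and summarized as a compact letter display.
#'
#' @param result a [MixedModelResult-class].
#' @param focus `"mean"`, `"SWC"` or `"VPD"`.
#' @param alpha significance level for the letters.
#' @return data.frame per cell: `species`, `elevation`, `present`,
#'   `estimate`, `se`, `df`, `lower`, `upper`, `letters`.
#' @export
lsMeans <- function(result, focus = c("mean", "SWC", "VPD"), alpha = 0.05) {
  focus <- match.arg(focus)
  d <- result@data
  prep <- satterthwaitePrep(result@fit)
  cells <- expand.grid(
    species = levels(d$species), elevation = levels(d$elevation),
    stringsAsFactors = FALSE
  )
  counts <- table(d$species, d$elevation)
  cells$present <- counts[cbind(cells$species, cells$elevation)] > 0
  h <- 0.5
  rowFor <- function(sp, el) {
    if (focus == "mean") return(lsCellRow(result, sp, el))
    dl <- list(); dl[[focus]] <- h
    dh <- lsCellRow(result, sp, el, dl)
    dl[[focus]] <- -h
    (dh - lsCellRow(result, sp, el, dl)) / (2 * h)
  }
  L <- matrix(NA_real_, nrow(cells), length(prep$beta))
  for (i in which(cells$present))
    L[i, ] <- rowFor(cells$species[i], cells$elevation[i])
  est <- se <- df <- rep(NA_real_, nrow(cells))
  for (i in which(cells$present)) {
    est[i] <- as.numeric(L[i, ] %*% prep$beta)
    se[i] <- sqrt(as.numeric(t(L[i, ]) %*% prep$V %*% L[i, ]))
    df[i] <- satterthwaiteDfRow(L[i, ], prep)
  }
  pres <- which(cells$present)
  k <- length(pres)
  pmat <- matrix(NA_real_, k, k,
                 dimnames = list(paste(cells$species[pres], cells$elevation[pres]),
                                 paste(cells$species[pres], cells$elevation[pres])))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a >= b) next
      i <- pres[a]; j <- pres[b]
      dl <- L[i, ] - L[j, ]
      sed <- sqrt(as.numeric(t(dl) %*% prep$V %*% dl))
      dfd <- satterthwaiteDfRow(dl, prep)
      tv <- abs(est[i] - est[j]) / sed
      ## ptukey needs df >= 1; a confounded contrast (df ~ 0) carries no
      ## information and is floored rather than dropped
      pmat[a, b] <- pmat[b, a] <-
        ptukey(tv * sqrt(2), nmeans = k, df = max(dfd, 1, na.rm = TRUE),
               lower.tail = FALSE)
    }
  }
  lets <- cldLetters(pmat, alpha)
  cells$estimate <- est
  cells$se <- se
  cells$df <- df
  cells$lower <- est - qt(0.975, df) * se
  cells$upper <- est + qt(0.975, df) * se
  cells$letters <- NA_character_
  cells$letters[pres] <- unname(lets)
  cells
}
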