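mkDaily <- function(trees, dates, jsMean = 5, foliated = TRUE) {
  expand.grid(tree = trees, date = dates, stringsAsFactors = FALSE) |>
    transform(jsSum = jsMean * 24, jsMean = jsMean, jsMax = jsMean * 2,
              nValid = 48L, valid = TRUE, foliated = foliated)
}

test_that("analysis table joins flux, drivers and metadata", {
  dates <- as.Date("2015-03-01") + 0:9
  daily <- mkDaily(c("a", "b", "c"), dates)
  drivers <- driversFromSwc(rep(20, 10), start = "2015-03-01")
  meta <- data.frame(tree = c("a", "b", "c"), species = "Ceiba",
                     elevation = "670", dbh = 50)
  tbl <- buildAnalysisTable(daily, list(`670` = drivers), meta)
  expect_equal(nrow(tbl), 30L)

  # one missing SWC day drops one row per tree, with the count reported
  drivers2 <- drivers; drivers2$swcMean[4] <- NA
  expect_message(
    tbl2 <- buildAnalysisTable(daily, list(`670` = drivers2), meta),
    "3 tree-days")
  expect_equal(nrow(tbl2), 27L)
  expect_equal(attr(tbl2, "nDropped"), 3L)

  # defoliated rows masked when the mask is on
  daily3 <- daily; daily3$foliated[daily3$tree == "a"] <- FALSE
  tbl3 <- buildAnalysisTable(daily3, list(`670` = drivers), meta)
  expect_false("a" %in% tbl3$tree)
  tbl3b <- buildAnalysisTable(daily3, list(`670` = drivers), meta,
                              maskDefoliated = FALSE)
  expect_equal(nrow(tbl3b), 30L)

  # driver table missing for a site is an explicit error
  meta$elevation <- "860"
  expect_error(buildAnalysisTable(daily, list(`670` = drivers), meta), "860")
})

test_that("SWC regression matches exact lines and a normal-equations oracle", {
  swc <- seq(5, 35, length.out = 20)
  tbl <- data.frame(jsMean = 0.3 * swc, swcMean = swc)
  fit <- suppressWarnings(regressFluxOnSWC(tbl))  # exact fit warns in summary.lm
  expect_equal(fit$slope, 0.3)
  expect_equal(fit$r2, 1)

  set.seed(17)
  tbl2 <- data.frame(jsMean = 2 + 0.2 * swc + rnorm(20, 0, 0.5),
                     swcMean = swc)
  fit2 <- regressFluxOnSWC(tbl2)
  # closed-form normal equations
  X <- cbind(1, tbl2$swcMean)
  betaHat <- solve(t(X) %*% X, t(X) %*% tbl2$jsMean)
  expect_equal(fit2$slope, betaHat[2, 1], tolerance = 1e-10)
  expect_equal(fit2$intercept, betaHat[1, 1], tolerance = 1e-10)

  expect_error(regressFluxOnSWC(tbl[1:5, ]), ">= 10")
  expect_error(
    regressFluxOnSWC(data.frame(jsMean = rnorm(12), swcMean = rep(9, 12))),
    "constant")
})

test_that("VPD regression is logarithmic and filters non-positive VPD", {
  vpd <- seq(0.5, 20, length.out = 30)
  tbl <- data.frame(jsMean = 1 + 2 * log(vpd), vpdMean = vpd,
                    label = "wet")
  fit <- suppressWarnings(regressFluxOnVPD(tbl, "wet"))
  expect_equal(fit$a, 1, tolerance = 1e-10)
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1)

  tbl$vpdMean[3] <- 0
  fit2 <- suppressWarnings(regressFluxOnVPD(tbl, "wet"))
  expect_equal(fit2$nExcluded, 1L)
  expect_equal(fit2$n, 29L)
})

test_that("Jsmax summary separates distant groups and shares letters for close ones", {
  mk <- function(meanA, meanB, seed) {
    set.seed(seed)
    data.frame(
      tree = rep(sprintf("t%02d", 1:40), each = 1),
      species = rep(c("A", "B"), each = 20),
      elevation = "670",
      jsMax = c(rnorm(20, meanA, 1), rnorm(20, meanB, 1)),
      label = "wet"
    )
  }
  out <- jsmaxSummary(mk(5, 15, 1))
  expect_equal(nrow(out), 2L)
  expect_true(out$letters[1] != out$letters[2])

  # identical populations share a letter in >= 90% of 100 seeds (alpha 0.05)
  shared <- vapply(1:100, function(s) {
    o <- jsmaxSummary(mk(10, 10, s))
    any(strsplit(o$letters[1], "")[[1]] %in% strsplit(o$letters[2], "")[[1]])
  }, logical(1))
  expect_gte(mean(shared), 0.90)

  # unreplicated groups: warning, no letters
  one <- data.frame(tree = c("t1", "t2"), species = c("A", "B"),
                    elevation = "670", jsMax = c(5, 9), label = "dry")
  expect_warning(o1 <- jsmaxSummary(one), "single|replication|two groups")
  expect_true(all(is.na(o1$letters)))
})

test_that("compact letter display separates exactly the significant pairs", {
  p <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p["a", "c"] <- p["c", "a"] <- 0.001
  lets <- cldLetters(p)
  expect_false(any(strsplit(lets["a"], "")[[1]] %in% strsplit(lets["c"], "")[[1]]))
  expect_true(any(strsplit(lets["a"], "")[[1]] %in% strsplit(lets["b"], "")[[1]]))
  expect_true(any(strsplit(lets["b"], "")[[1]] %in% strsplit(lets["c"], "")[[1]]))
  # nothing significant: everyone shares one letter
  expect_equal(unname(cldLetters(matrix(1, 3, 3))), rep("a", 3))
})
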