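test_that("Satterthwaite df matches the classical balanced-design values", {
  # balanced between-tree factor: 10 trees x 6 obs, 2 groups.
  # Classical split-plot result: F for the group effect equals the one-way
  # ANOVA on tree means, with denominator df = trees - 2.
  set.seed(21)
  nTree <- 10; m <- 6
  tree <- rep(sprintf("t%02d", 1:nTree), each = m)
  grp <- factor(rep(rep(c("A", "B"), each = nTree / 2), each = m))
  y <- 2 + 0.8 * (grp == "B") +
    rep(rnorm(nTree, 0, 1), each = m) + rnorm(nTree * m, 0, 0.7)
  d <- data.frame(y = y, grp = grp, tree = tree)
  fit <- lme4::lmer(y ~ grp + (1 | tree), data = d, REML = TRUE)
  av <- satterthwaiteAnova(fit)
  expect_equal(av["grp", "DenDF"], nTree - 2, tolerance = 1e-3)
  # oracle F from tree means
  tm <- aggregate(y ~ tree + grp, d, mean)
  a1 <- anova(lm(y ~ grp, tm))
  expect_equal(av["grp", "F value"], a1["grp", "F value"], tolerance = 1e-5)
  expect_equal(av["grp", "Pr(>F)"],
               a1["grp", "Pr(>F)"], tolerance = 1e-5)
})

test_that("R2 decomposition follows the variance-partition formula", {
  # strong fixed effects, known variance components; with n large the
  # realized variances pin the ratio near its target
  sim <- simulateResponseTable(
    nTrees = 60, nDays = 120,
    beta = c(VPD = 0.25, SWC = 0.25), sdTree = 1, sdResid = 1, seed = 4
  )
  mm <- fitMixedModel(sim$table)
  s2f <- var(as.vector(sim$design %*% sim$beta))
  target <- c(marginal = s2f / (s2f + 2), conditional = (s2f + 1) / (s2f + 2))
  r2 <- r2Nakagawa(mm)
  expect_equal(unname(r2), unname(target), tolerance = 0.08)
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_true(all(varianceComponents(mm) >= 0))
})

test_that("near-deterministic data drive both R2 to one", {
  sim <- simulateResponseTable(
    nTrees = 24, nDays = 30, beta = c(VPD = 0.5, SWC = 0.3),
    sdTree = 0, sdResid = 1e-4, seed = 8
  )
  mm <- fitMixedModel(sim$table)
  expect_gt(mm@r2m, 0.999)
  expect_gt(mm@r2c, 0.999)
  expect_true(mm@singular)  # tree variance collapses to zero and is flagged
})

test_that("the model encodes the study's six interactions and drops empty cells", {
  sim <- simulateResponseTable(nTrees = 36, nDays = 20, seed = 10)
  tbl <- sim$table
  # empty the evergreen x top-elevation cell, as in the field design
  tbl <- tbl[!(tbl$species == "Capparis" & tbl$elevation == 1100), ]
  mm <- fitMixedModel(tbl)
  av <- anovaTable(mm)
  expect_setequal(rownames(av),
    c("SWC", "VPD", "species", "elevation", "DBH", "SWC:VPD",
      "SWC:species", "SWC:elevation", "VPD:species", "VPD:elevation",
      "species:elevation"))
  # (4-1)(3-1) = 6 minus one inestimable contrast for the empty cell
  expect_equal(av["species:elevation", "NumDF"], 5)
  expect_equal(av["species", "NumDF"], 3)
  expect_equal(av["elevation", "NumDF"], 2)
})

test_that("ls-means rank driver sensitivities and report absent cells", {
  # species1 (Capparis under sum coding) gets an extra VPD response
  sim <- simulateResponseTable(
    nTrees = 36, nDays = 60,
    beta = c(VPD = 0.4, `VPD:species1` = 0.3),
    sdTree = 0.3, sdResid = 0.7, seed = 12
  )
  tbl <- sim$table
  tbl <- tbl[!(tbl$species == "Capparis" & tbl$elevation == 1100), ]
  mm <- fitMixedModel(tbl)
  ls <- lsMeans(mm, focus = "VPD")
  absent <- ls[ls$species == "Capparis" & ls$elevation == "1100", ]
  expect_false(absent$present)
  expect_true(is.na(absent$estimate))
  for (el in c("670", "860")) {
    sub <- ls[ls$elevation == el & ls$present, ]
    expect_equal(sub$species[which.max(sub$estimate)], "Capparis")
  }
  # recovered sensitivity close to the generating one (0.4 + 0.3)
  expect_equal(ls$estimate[ls$species == "Capparis" & ls$elevation == "670"],
               0.7, tolerance = 0.1)
})

test_that("ls-means share letters when species are exchangeable", {
  sim <- simulateResponseTable(
    nTrees = 36, nDays = 40, beta = c(VPD = 0.3),
    sdTree = 0.3, sdResid = 0.7, seed = 14
  )
  mm <- fitMixedModel(sim$table)
  ls <- lsMeans(mm, focus = "VPD")
  # all cells generated identically: a common letter must exist
  common <- Reduce(intersect, strsplit(ls$letters[ls$present], ""))
  expect_gt(length(common), 0)
})

test_that("coefficient table covers the generating coefficients", {
  sim <- simulateResponseTable(
    nTrees = 30, nDays = 40,
    beta = c(VPD = 0.4, SWC = 0.05, `SWC:species1` = 0.2),
    seed = 16
  )
  mm <- fitMixedModel(sim$table)
  ct <- coefTable(mm)
  expect_equal(rownames(ct), names(sim$beta))
  covered <- ct$lower <= sim$beta & sim$beta <= ct$upper
  expect_gt(mean(covered), 0.8)  # single realization, near-nominal
  expect_true(all(ct$df > 0))
})
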