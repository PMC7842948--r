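test_that("response curves anchor at the intercept-only occupancy", {
  fx <- fixture9()
  sm <- summarizePosterior(fx$post)
  m <- posteriorDraws(fx$post)
  for (cov in c("depth", "canopy")) {
    rc <- responseCurve(fx$post, cov, fx$covs, nPoints = 21)
    expect_true(all(rc$mean > 0 & rc$mean < 1))
    expect_true(all(rc$lo <= rc$mean & rc$mean <= rc$hi))
    # at the covariate mean (standardized 0) the curve equals the
    # intercept-only value, identically across covariates
    for (sp in c("GREG", "ROSP")) {
      a <- m[, sprintf("alpha_psi[%s]", sp)]
      ctr <- fx$post@covInfo$center[cov]
      scl <- fx$post@covInfo$scale[cov]
      rcSp <- rc[rc$species == sp, ]
      atMean <- approx(rcSp$value, rcSp$mean, xout = ctr)$y
      expect_equal(unname(atMean), mean(plogis(a)), tolerance = 0.02)
    }
  }
  expect_error(responseCurve(fx$post, "salinity", fx$covs), "unknown")
})

test_that("response-curve geometry follows the coefficients", {
  # hand-built posterior: zero coefficients give a flat curve; negative
  # quadratic with zero linear coefficient peaks at the covariate mean
  nd <- 40
  draws <- array(0, c(2, nd, 5), dimnames = list(NULL, NULL, c(
    "alpha_psi[A]", "beta[depth,A]", "beta[depth_sq,A]", "alpha_p[A]",
    "p[A]")))
  draws[, , "alpha_psi[A]"] <- 0.4
  draws[, , "p[A]"] <- plogis(0)
  post <- new("occuPosterior", draws = draws, species = "A",
              coefNames = c("depth", "depth_sq"),
              config = mcmcConfig(nIter = 80, nBurnin = 0, thin = 1,
                                  nChains = 2),
              covInfo = list(center = c(depth = 20), scale = c(depth = 10),
                             min = c(depth = 0), max = c(depth = 60),
                             predictors = c("depth", "depth_sq")))
  flat <- responseCurve(post, "depth", nPoints = 15)
  expect_true(all(abs(flat$mean - plogis(0.4)) < 1e-12))
  post2 <- post
  post2@draws[, , "beta[depth_sq,A]"] <- -0.7
  par <- responseCurve(post2, "depth", nPoints = 61)
  expect_equal(par$value[which.max(par$mean)], 20, tolerance = 1e-9)
  expect_true(all(diff(par$mean[par$value < 20]) > 0))
  expect_true(all(diff(par$mean[par$value > 20]) < 0))
})

test_that("plug-in maps reproduce in-sample occupancy probabilities", {
  fx <- fixture9()
  map <- predictOccupancyMap(fx$post, fx$covs, scenario = "baseline")
  expect_equal(nrow(map), nSites(fx$covs) * 9)
  # cell-by-cell agreement with occupancyProb under posterior means
  sm <- summarizePosterior(fx$post)
  means <- setNames(sm$mean, sm$param)
  X <- buildDesignMatrix(standardizeCovariates(fx$covs),
                         predictors = fx$post@coefNames)
  sp <- "WHIB"
  psi <- occupancyProb(means[sprintf("alpha_psi[%s]", sp)],
                       means[sprintf("beta[%s,%s]", fx$post@coefNames, sp)],
                       X)
  expect_equal(map$psi[map$species == sp], unname(psi), tolerance = 1e-12)
  expect_true(all(map$psi > 0 & map$psi < 1))
})

test_that("map predictions respond monotonically to a monotone coefficient", {
  # two cells differing only in one covariate with positive linear effect
  nd <- 20
  draws <- array(0, c(2, nd, 4), dimnames = list(NULL, NULL, c(
    "alpha_psi[A]", "beta[x,A]", "alpha_p[A]", "p[A]")))
  draws[, , "beta[x,A]"] <- 1.2
  post <- new("occuPosterior", draws = draws, species = "A",
              coefNames = "x",
              config = mcmcConfig(nIter = 40, nBurnin = 0, thin = 1,
                                  nChains = 2),
              covInfo = list(center = c(x = 0), scale = c(x = 1),
                             min = c(x = -2), max = c(x = 2),
                             predictors = "x"))
  covs <- makeCovs(cbind(x = c(-1, 0, 1)))
  map <- predictOccupancyMap(post, covs)
  expect_true(all(diff(map$psi) > 0))
  # all-mean covariates give the inverse-logit of the intercept
  expect_equal(map$psi[2], plogis(0), tolerance = 1e-12)
  # scenario outside the training range warns but still predicts
  expect_warning(predictOccupancyMap(post, makeCovs(cbind(x = c(0, 5)))),
                 "training range")
})

test_that("scenario comparison computes percent differences and summaries", {
  base <- data.frame(site = rep(c("a", "b"), 2),
                     easting = 1, northing = 1,
                     species = rep(c("S1", "S2"), each = 2),
                     psi = c(0.5, 0.5, 0.25, 0.4), scenario = "base")
  alt <- base
  alt$psi <- c(0.6, 0.6, 0.25, 0.2)
  d <- compareScenarios(base, alt)
  expect_equal(d$pctDiff, c(20, 20, 0, -50))
  summ <- attr(d, "summary")
  expect_equal(summ$mean[summ$species == "S1"], 20)
  expect_equal(summ$shareImproving[summ$species == "S2"], 0)
  # identical scenarios: all zero
  expect_true(all(compareScenarios(base, base)$pctDiff == 0))
  # antisymmetry up to the denominator change
  rev <- compareScenarios(alt, base)
  expect_equal(rev$pctDiff[1], 100 * (0.5 - 0.6) / 0.6)
  bad <- alt[-1, ]
  expect_error(compareScenarios(base, bad), "do not match")
})

test_that("scenario shifts propagate through fitted effects with the right
           sign", {
  fx <- fixture9()
  sm <- summarizePosterior(fx$post)
  base <- predictOccupancyMap(fx$post, fx$covs, scenario = "baseline")
  # raise days-dry by half an SD everywhere
  alt <- fx$covs
  shift <- 0.5 * sd(fx$covs@values[, "days_dry"])
  alt@values[, "days_dry"] <- alt@values[, "days_dry"] + shift
  suppressWarnings(mapAlt <- predictOccupancyMap(fx$post, alt, "drier"))
  d <- compareScenarios(base, mapAlt)
  summ <- attr(d, "summary")
  # species fitted with a negative days-dry effect at the evaluation point
  # must decline on average
  for (sp in fx$post@species) {
    b <- sm$mean[sm$param == sprintf("beta[days_dry,%s]", sp)]
    if (b < -0.3) expect_lt(summ$mean[summ$species == sp], 0)
  }
})

test_that("ASCII grid export writes a readable raster header", {
  dir <- withr::local_tempdir()
  grid <- data.frame(site = sprintf("s%d", 1:4),
                     easting = c(0, 2000, 0, 2000),
                     northing = c(0, 0, 2000, 2000),
                     species = "A", psi = c(0.1, 0.2, 0.3, 0.4),
                     scenario = "base")
  f <- file.path(dir, "a.asc")
  writeAsciiGrid(grid, "A", f, cellSize = 2000)
  lines <- readLines(f)
  expect_match(lines[1], "^ncols 2$")
  expect_match(lines[2], "^nrows 2$")
  vals <- as.numeric(unlist(strsplit(trimws(lines[7:8]), " ")))
  expect_equal(vals, c(0.3, 0.4, 0.1, 0.2))  # north row first
  expect_error(writeAsciiGrid(grid, "B", f), "not present")
})
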