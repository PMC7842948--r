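test_that("Savage-Dickey ratio matches the analytic normal-normal value", {
  # prior Normal(0, precision 0.001): density at 0 is 0.012615;
  # posterior Normal(5, 1): density at 0 is 1.4867e-6; ln BF about 9.05
  set.seed(11)
  draws <- rnorm(20000, 5, 1)
  pr <- communityPrior("literal", tau0 = 0.001)
  analytic <- dnorm(0, 0, sqrt(1000), log = TRUE) - dnorm(0, 5, 1, log = TRUE)
  expect_equal(analytic, 9.05, tolerance = 0.001)
  expect_equal(as.numeric(savageDickeyLnBF(draws, pr)), analytic,
               tolerance = 0.3 / analytic)
  # KDE and normal-approximation estimators agree when the null is interior
  set.seed(14)
  mid <- rnorm(20000, 0.8, 0.5)
  expect_equal(as.numeric(savageDickeyLnBF(mid, pr, method = "kde")),
               as.numeric(savageDickeyLnBF(mid, pr, method = "normal")),
               tolerance = 0.05)
})

test_that("no updating yields ln BF near zero; null-concentrated posteriors
           yield negative evidence", {
  pr <- communityPrior("literal", tau0 = 0.001)
  set.seed(12)
  priorDraws <- rnorm(20000, 0, sqrt(1000))
  expect_equal(as.numeric(savageDickeyLnBF(priorDraws, pr)), 0,
               tolerance = 0.15)
  # posterior tight around the null: strong evidence FOR the null
  nullDraws <- rnorm(5000, 0, 0.05)
  expect_lt(as.numeric(savageDickeyLnBF(nullDraws, pr)), 0)
  # exactly degenerate at 0
  lnbf <- savageDickeyLnBF(rep(0, 1000), pr)
  expect_true(lnbf < 0)
  # far-from-null degenerate posterior caps at +Inf with the flag set
  far <- savageDickeyLnBF(rep(7, 1000), pr)
  expect_true(is.infinite(far) && far > 0)
  expect_true(attr(far, "capped"))
  expect_error(savageDickeyLnBF(rnorm(100), pr), "500")
})

test_that("decisive and negligible flags follow the ln-BF thresholds", {
  # decisive bound is ln(100)
  expect_equal(4.61, log(100), tolerance = 0.002)
  pr <- communityPrior("literal", tau0 = 0.001)
  set.seed(13)
  strong <- savageDickeyLnBF(rnorm(5000, 6, 0.8), pr)
  expect_true(attr(strong, "decisive"))
  expect_false(attr(strong, "negligible"))
  weak <- savageDickeyLnBF(rnorm(5000, 0, 0.2), pr)
  expect_false(attr(weak, "decisive"))
  expect_true(attr(weak, "negligible"))
})

test_that("Dunn-Smyth residuals hit their analytic quantiles", {
  # y = 1, pi = 0.5: u interval (0.5, 1), midpoint 0.75
  expect_equal(dunnSmythResiduals(1, 0.5, uFrac = 0.5), qnorm(0.75),
               tolerance = 1e-12)
  # well-fit zero: y = 0 with pi near 0 gives a residual near 0
  expect_equal(dunnSmythResiduals(0, 1e-8, uFrac = 0.5), qnorm(0.5 + 5e-9),
               tolerance = 1e-6)
  expect_equal(dunnSmythResiduals(0, 1e-8, uFrac = 0.5), 0, tolerance = 1e-6)
  expect_error(dunnSmythResiduals(1, 1), "strictly inside")
  expect_error(dunnSmythResiduals(1, 0), "strictly inside")
  expect_error(dunnSmythResiduals(2, 0.5), "binary")
  # deterministic given seed
  set.seed(99); pi <- runif(50, 0.1, 0.9); yy <- rbinom(50, 1, pi)
  expect_identical(dunnSmythResiduals(yy, pi, seed = 3),
                   dunnSmythResiduals(yy, pi, seed = 3))
})

test_that("residuals from a correctly specified model are standard normal", {
  set.seed(21)
  n <- 10000
  pi <- runif(n, 0.02, 0.98)
  y <- rbinom(n, 1, pi)
  r <- dunnSmythResiduals(y, pi, seed = 22)
  ks <- ks.test(r, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(r), 0, tolerance = 0.05)
  expect_equal(sd(r), 1, tolerance = 0.05)
})

test_that("residual-trend adequacy flag behaves at the extremes", {
  f <- seq(0.1, 0.9, length.out = 40)
  # residuals identically zero: slope 0, adequate
  chk0 <- residualFitCheck(rep(0, 40), f)
  expect_equal(chk0$slope, 0, tolerance = 1e-12)
  expect_true(chk0$adequate)
  # residuals equal to fitted: slope 1, clear trend, inadequate
  chk1 <- residualFitCheck(f, f)
  expect_equal(chk1$slope, 1, tolerance = 1e-10)
  expect_false(chk1$adequate)
  expect_error(residualFitCheck(rep(0, 5), f[1:5]), "at least 10")
})

test_that("AUC equals the pairwise concordance oracle", {
  expect_equal(aucOccu(c(1, 0, 1), c(0.9, 0.2, 0.6)), 1)
  expect_equal(aucOccu(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(aucOccu(c(1, 0), c(0.2, 0.9)), 0)
  expect_error(aucOccu(c(1, 1), c(0.2, 0.9)), "both outcome classes")
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    obs <- rbinom(n, 1, 0.4)
    if (length(unique(obs)) < 2) next
    pred <- round(runif(n), 2)             # induce ties
    expect_equal(aucOccu(obs, pred), pairwiseAuc(obs, pred))
  }
  # pROC cross-check where available
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(32)
    obs <- rbinom(150, 1, 0.5); pred <- runif(150)
    expect_equal(aucOccu(obs, pred),
                 as.numeric(pROC::auc(pROC::roc(obs, pred, quiet = TRUE))))
  }
})

test_that("posterior AUC summaries respect degeneracy and sign flips", {
  fx <- fixture9()
  auc <- aucPosterior(fx$post, fx$sim, fx$covs, maxDraws = 60)
  expect_true(all(auc$mean >= auc$lo & auc$mean <= auc$hi))
  expect_true(all(auc$mean > 0.5))
  expect_true(all(auc$lo >= 0 & auc$hi <= 1))
  # a degenerate posterior (single repeated draw) has a zero-width interval
  one <- fx$post@draws[1, 1, , drop = TRUE]
  deg <- fx$post
  for (ch in 1:dim(deg@draws)[1]) deg@draws[ch, , ] <-
    matrix(one, dim(deg@draws)[2], length(one), byrow = TRUE)
  aucD <- aucPosterior(deg, fx$sim, fx$covs, maxDraws = 10)
  expect_equal(aucD$lo, aucD$hi)
  # flipping every parameter sign anti-predicts
  flip <- deg
  flip@draws <- -deg@draws
  aucF <- aucPosterior(flip, fx$sim, fx$covs, maxDraws = 5, type = "psi")
  expect_true(all(aucF$mean < 0.5))
})

test_that("a well-specified community fit is adequate and discriminates", {
  fx <- fixture9()
  res <- occuResiduals(fx$post, fx$sim, fx$covs, seed = 3)
  expect_equal(nrow(res), nSites(fx$sim) * 9)
  chk <- residualFitCheck(res$residual, res$fitted, res$species)
  expect_true(all(chk$adequate))
  auc <- aucPosterior(fx$post, fx$sim, fx$covs, maxDraws = 60)
  # the community-average discrimination clears the conventional 0.7
  # adequacy bar; individual species vary with their community draw
  expect_gt(mean(auc$mean), 0.7)
  expect_true(all(auc$mean > 0.65))
})

test_that("Bayes-factor table mirrors the species-by-predictor layout", {
  fx <- fixture9()
  bf <- bayesFactorTable(fx$post)
  expect_equal(nrow(bf), 9 * 9)
  expect_identical(names(bf), c("species", "predictor", "lnBF", "decisive",
                                "negligible"))
  expect_true(all(bf$decisive == (bf$lnBF > 4.61)))
  expect_true(all(bf$negligible == (bf$lnBF < 0)))
  # strong simulated days-dry effects should be decisive for most species
  dd <- bf[bf$predictor == "days_dry", ]
  expect_gt(sum(dd$decisive), 4)
})
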