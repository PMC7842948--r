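test_that("chain configuration is validated and sets retained-draw counts", {
  cfg <- mcmcConfig()
  expect_equal((cfg@nIter - cfg@nBurnin) %/% cfg@thin, 1000L)
  expect_equal(cfg@nChains, 3L)
  expect_error(mcmcConfig(nIter = 1000, nBurnin = 1000), "nBurnin")
  expect_error(mcmcConfig(thin = 0), "thin")
  expect_error(mcmcConfig(nChains = 1), "chains")
})

test_that("fit returns the configured draw layout and is deterministic", {
  dat <- simpleHistory(60, 3, 0.6, 0.7, seed = 41)
  cfg <- mcmcConfig(nIter = 300, nBurnin = 100, thin = 4, nChains = 2,
                    seed = 8, prior = communityPrior("literal"))
  post <- fitOccu(dat, NULL, cfg)
  expect_equal(dim(post@draws), c(2L, 50L, 3L))
  expect_identical(dimnames(post@draws)[[3]],
                   c("alpha_psi[sp01]", "alpha_p[sp01]", "p[sp01]"))
  expect_identical(post@draws, fitOccu(dat, NULL, cfg)@draws)
})

test_that("R-hat matches the PSRF formula and flags disjoint chains", {
  # hand evaluation: chains (1,2,3,4) and (2,3,4,5); W = 5/3, B = 2,
  # pooled variance estimate (3/4)W + B/4 = 1.75, R-hat = sqrt(1.75/W)
  ch <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(unname(gelmanRhat(ch)), sqrt(1.05), tolerance = 1e-12)
  # identical long stationary streams
  set.seed(2); s <- rnorm(1000)
  expect_true(abs(gelmanRhat(rbind(s, s)) - 1) < 0.01)
  # disjoint constant chains
  expect_equal(unname(gelmanRhat(rbind(rep(1, 4), rep(5, 4)))), Inf)
  # constant identical chains are defined as converged
  expect_equal(unname(gelmanRhat(rbind(rep(2, 4), rep(2, 4)))), 1)
  expect_error(gelmanRhat(matrix(1:4, 1)), "2 chains")
})

test_that("split R-hat detects within-chain drift that plain R-hat misses", {
  tr <- seq(0, 3, length.out = 500)
  ch <- rbind(tr, tr)                       # same drift in both chains
  expect_lt(gelmanRhat(ch), 1.01)
  expect_gt(gelmanRhat(ch, split = TRUE), 1.5)
  expect_gt(gelmanRhat(ch, rankNormalized = TRUE), 1.5)
})

test_that("posterior summary implements the CrI-excludes-zero rule", {
  mk <- function(v) new("occuPosterior",
                        draws = array(rep(v, 2), c(2, length(v), 1),
                                      dimnames = list(NULL, NULL, "b")),
                        species = "sp", coefNames = character(0),
                        config = mcmcConfig(nIter = 40, nBurnin = 20,
                                            thin = 1, nChains = 2),
                        covInfo = NULL)
  sm <- summarizePosterior(mk(rep(2, 20)))
  expect_equal(sm$mean, 2); expect_equal(sm$lo, 2); expect_equal(sm$hi, 2)
  expect_true(sm$important)
  expect_false(summarizePosterior(mk(rep(0, 20)))$important)
  sym <- summarizePosterior(mk(c(-(1:10), 1:10) / 5))
  expect_equal(sym$mean, 0)
  expect_false(sym$important)
  set.seed(5)
  smn <- summarizePosterior(mk(rnorm(40000)))
  expect_equal(smn$lo, -1.96, tolerance = 0.05 / 1.96)
  expect_equal(smn$hi, 1.96, tolerance = 0.05 / 1.96)
})

test_that("sampler posterior matches a dense-grid reference posterior", {
  n <- 300; K <- 5
  dat <- simpleHistory(n, K, 0.55, 0.30, seed = 43)
  cfg <- mcmcConfig(nIter = 8000, nBurnin = 2000, thin = 3, seed = 17,
                    prior = communityPrior("literal"))
  post <- fitOccu(dat, NULL, cfg)
  sm <- summarizePosterior(post)

  # independent oracle: 2-d quadrature of the marginal posterior
  d <- apply(dat@y, 1, sum)
  cnt <- tabulate(d + 1, K + 1)            # counts of d = 0..K
  aGrid <- seq(-2.5, 2.5, length.out = 201)
  bGrid <- seq(-3.5, 1.5, length.out = 201)
  ll <- outer(aGrid, bGrid, Vectorize(function(a, b) {
    psi <- plogis(a); p <- plogis(b)
    sum(cnt * log(psi * p^(0:K) * (1 - p)^(K:0) + (1 - psi) * c(1, rep(0, K)))) +
      dnorm(a, 0, sqrt(1000), log = TRUE) + dnorm(b, 0, sqrt(1000), log = TRUE)
  }))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  refA <- sum(rowSums(w) * aGrid)
  refB <- sum(colSums(w) * bGrid)
  expect_equal(sm$mean[sm$param == "alpha_psi[sp01]"], refA, tolerance = 0.08)
  expect_equal(sm$mean[sm$param == "alpha_p[sp01]"], refB, tolerance = 0.08)
})

test_that("perfect-detection data concentrate the occupancy intercept at the
           empirical logit", {
  set.seed(44)
  n <- 400; z <- rbinom(n, 1, 0.4)
  y <- array(rep(z, 2), c(n, 2, 1))        # detected on every visit iff present
  dat <- makeHistory(y, z = matrix(z, ncol = 1))
  cfg <- mcmcConfig(nIter = 4000, nBurnin = 1500, thin = 3, seed = 4,
                    prior = communityPrior("literal"))
  post <- fitOccu(dat, NULL, cfg)
  sm <- summarizePosterior(post)
  expect_equal(sm$mean[sm$param == "alpha_psi[sp01]"], qlogis(mean(z)),
               tolerance = 0.2)
})

test_that("community priors shrink a rare species toward the community", {
  set.seed(45)
  n <- 800
  x <- rnorm(n)
  covs <- makeCovs(cbind(x = x))
  par <- makeParams(alphaPsi = rep(0, 4),
                    beta = rep(0.8, 4),
                    alphaP = qlogis(c(0.35, 0.30, 0.25, 0.04)),
                    coefNames = "x")
  des <- surveyDesign(nCells = n, nYears = 1, nVisits = 5, nSpecies = 4)
  sim <- simulateDetections(par, covs, des, seed = 46)
  cfgH <- mcmcConfig(nIter = 4000, nBurnin = 1500, thin = 3, seed = 6,
                     prior = communityPrior("hierarchical"))
  postH <- fitOccu(sim, covs, cfgH)
  smH <- summarizePosterior(postH)

  rare <- sim@species[4]
  yR <- sim@y[, , 4, drop = FALSE]
  datR <- makeHistory(yR, species = rare)
  cfgL <- mcmcConfig(nIter = 4000, nBurnin = 1500, thin = 3, seed = 6,
                     prior = communityPrior("literal"))
  postL <- fitOccu(datR, covs, cfgL)
  smL <- summarizePosterior(postL)

  sdH <- smH$sd[smH$param == sprintf("beta[x,%s]", rare)]
  sdL <- smL$sd[smL$param == sprintf("beta[x,%s]", rare)]
  expect_lte(sdH, sdL)
})

test_that("invalid detection arrays are rejected at construction", {
  expect_error(new("detectionHistory",
                   y = array(2L, c(1, 1, 1)), siteIds = "s1", years = 1L,
                   species = "a", z = NULL, trueParams = NULL),
               "0, 1 or NA")
  # a detection recorded where the latent state says unoccupied
  y <- array(1L, c(1, 1, 1))
  expect_error(new("detectionHistory", y = y, siteIds = "s1", years = 1L,
                   species = "a", z = matrix(0L, 1, 1), trueParams = NULL),
               "z == 0")
})
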