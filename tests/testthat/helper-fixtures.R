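# shared fixtures and independent oracles, built in code at test time

# minimal detection history from an explicit (site x visit x species) array
makeHistory <- function(y, z = NULL, species = NULL) {
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(dim(y)[3L]))
  dimnames(y) <- list(NULL, NULL, species)
  new("detectionHistory", y = y, siteIds = sprintf("s%03d", seq_len(dim(y)[1L])),
      years = rep(1L, dim(y)[1L]), species = species, z = z,
      trueParams = NULL)
}

# intercept-only single/multi-species dataset simulated outside the package
# machinery (independent of simulateDetections)
simpleHistory <- function(n, K, psi, p, seed, species = NULL) {
  set.seed(seed)
  I <- length(psi)
  y <- array(NA_integer_, c(n, K, I))
  z <- matrix(rbinom(n * I, 1L, rep(psi, each = n)), n, I)
  for (i in seq_len(I)) y[, , i] <- matrix(rbinom(n * K, 1L, p[i] * z[, i]), n, K)
  makeHistory(y, z = z, species = species)
}

# covariateData built directly from a matrix
makeCovs <- function(values, standardized = FALSE) {
  new("covariateData", values = values,
      siteIds = sprintf("s%03d", seq_len(nrow(values))),
      year = rep(1L, nrow(values)), center = numeric(0),
      scale = numeric(0), standardized = standardized)
}

# brute-force marginal likelihood oracle: enumerate every latent
# configuration z in {0,1}^(J x I) and sum prod P(X | z) P(z)
bruteLoglik <- function(params, data, X) {
  y <- data@y
  J <- dim(y)[1L]; I <- dim(y)[3L]
  psi <- plogis(sweep(X %*% t(params@beta), 2L, params@alphaPsi, "+"))
  p <- plogis(params@alphaP)
  cells <- expand.grid(rep(list(0:1), J * I))
  tot <- 0
  for (r in seq_len(nrow(cells))) {
    z <- matrix(as.numeric(cells[r, ]), J, I)
    pr <- 1
    for (j in seq_len(J)) for (i in seq_len(I)) {
      pr <- pr * (if (z[j, i] == 1) psi[j, i] else 1 - psi[j, i])
      for (k in seq_len(dim(y)[2L])) {
        x <- y[j, k, i]
        if (is.na(x)) next
        pd <- p[i] * z[j, i]
        pr <- pr * (if (x == 1) pd else 1 - pd)
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# O(n^2) pairwise AUC oracle, ties counted one half
pairwiseAuc <- function(obs, pred) {
  pos <- pred[obs == 1]; neg <- pred[obs == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# small speciesParams constructor
makeParams <- function(alphaPsi, beta = NULL, alphaP, coefNames = character(0),
                       species = NULL) {
  I <- length(alphaPsi)
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(I))
  if (is.null(beta)) beta <- matrix(0, I, 0)
  new("speciesParams", alphaPsi = alphaPsi,
      beta = matrix(beta, I, length(coefNames)), alphaP = alphaP,
      coefNames = coefNames, species = species,
      hyperMu = numeric(0), hyperSigma = numeric(0))
}

# one moderate 9-species hierarchical fit shared by several diagnostic
# tests (built lazily, cached for the session)
.fix9 <- new.env()
fixture9 <- function() {
  if (is.null(.fix9$fit)) {
    des <- surveyDesign(nCells = 300, nYears = 5, nSpecies = 9, seed = 7)
    par <- exampleCommunityParams(9, seed = 7)
    covs <- generateCovariates(des)
    sim <- simulateDetections(par, covs, des, seed = 11)
    cfg <- mcmcConfig(nIter = 3000, nBurnin = 1500, thin = 3, seed = 5)
    .fix9$fit <- list(post = fitOccu(sim, covs, cfg), sim = sim,
                      covs = covs, par = par, des = des)
  }
  .fix9$fit
}
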