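#' Default site-covariate specifications
#'
#' Marginal specifications for the six site covariates driving wading-bird
#' occupancy in the Everglades sampling frame: breeding-season water depth
#' (cm), water recession rate (cm/day, positive = receding), days dry over
#' the previous three years, proportion tree canopy cover, and the easting /
#' northing cell-centroid coordinates (m).  Means, SDs and ranges match the
#' observed landscape; the three hydrologic covariates also enter the model
#' quadratically.
#'
#' Marginal families (\code{dist}) are a modelling choice of the generator:
#' truncated normal for depth, recession and the coordinates; zero-inflated
#' truncated normal for days-dry (a point mass of cells that never dried);
#' a rescaled Beta for canopy cover.  Parameters of each family are
#' moment-matched so the generated sample reproduces the stated mean and SD.
#'
#' @return data.frame with columns \code{name, mean, sd, min, max,
#'   quadratic, dist}.
#' @export
defaultCovariateSpecs <- function() {
  data.frame(
    name = c("depth", "recession", "days_dry", "canopy", "easting", "northing"),
    mean = c(17.28, 0.02, 235.20, 0.07, 528048.8, 2863767),
    sd   = c(17.38, 0.13, 262.26, 0.11, 22477.46, 35566.75),
    min  = c(0, -0.45, 0, 0, 467021, 2792200),
    max  = c(98.65, 0.55, 1097, 0.64, 575021, 2948200),
    quadratic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dist = c("tnorm", "tnorm", "zi_tnorm", "beta", "tnorm", "tnorm"),
    stringsAsFactors = FALSE
  )
}

#' Default species codes and per-visit detection probabilities
#'
#' The nine focal wading-bird taxa with representative per-visit detection
#' probabilities spanning the observed range (about 0.04 for the rarely
#' detected roseate spoonbill and little blue heron up to 0.51 for the
#' great egret).
#'
#' @return named numeric vector of detection probabilities.
#' @export
defaultDetectionProbs <- function() {
  c(GBHE = 0.179, GLIB = 0.059, GREG = 0.511, LBHE = 0.042, ROSP = 0.042,
    SDH = 0.131, SWH = 0.168, WHIB = 0.356, WOST = 0.151)
}

# deterministic substream seed for stage k under master seed
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483629)
}

# mean / sd of Normal(mu, sigma) truncated to [a, b]
.tnMoments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z < 1e-12) return(c(mean = NA_real_, sd = NA_real_))
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# underlying normal parameters whose [a,b]-truncation has the target moments
.tnSolve <- function(mean, sd, a, b) {
  obj <- function(par) {
    mom <- .tnMoments(par[1L], exp(par[2L]), a, b)
    if (anyNA(mom)) return(1e10)
    ((mom[1L] - mean) / sd)^2 + ((mom[2L] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

# inverse-CDF sampler for the truncated normal
.rTruncNorm <- function(n, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  u <- stats::runif(n, pa, pb)
  stats::qnorm(u, mu, sigma)
}

# one covariate column of length n from a single spec row
.drawCovariate <- function(spec, n) {
  if (spec$sd < 0) stop("covariate '", spec$name, "': sd must be nonnegative")
  if (spec$min > spec$mean || spec$mean > spec$max)
    stop("covariate '", spec$name, "': need min <= mean <= max")
  if (spec$sd == 0) return(rep(spec$mean, n))
  x <- switch(spec$dist,
    tnorm = {
      par <- .tnSolve(spec$mean, spec$sd, spec$min, spec$max)
      .rTruncNorm(n, par["mu"], par["sigma"], spec$min, spec$max)
    },
    zi_tnorm = {
      # point mass at the range minimum plus a truncated-normal body,
      # with the body moment-matched so the mixture hits the target moments
      pZero <- 0.3
      mc <- (spec$mean - pZero * spec$min) / (1 - pZero)
      ex2 <- (spec$sd^2 + spec$mean^2 - pZero * spec$min^2) / (1 - pZero)
      vc <- ex2 - mc^2
      if (vc <= 0) stop("covariate '", spec$name,
                        "': moments infeasible for zero-inflated family")
      par <- .tnSolve(mc, sqrt(vc), spec$min, spec$max)
      zero <- stats::runif(n) < pZero
      out <- .rTruncNorm(n, par["mu"], par["sigma"], spec$min, spec$max)
      out[zero] <- spec$min
      out
    },
    beta = {
      w <- spec$max - spec$min
      m <- (spec$mean - spec$min) / w
      v <- (spec$sd / w)^2
      if (v >= m * (1 - m))
        stop("covariate '", spec$name, "': variance too large for Beta family")
      ab <- m * (1 - m) / v - 1
      spec$min + w * stats::rbeta(n, m * ab, (1 - m) * ab)
    },
    stop("unknown distribution family '", spec$dist, "' for covariate '",
         spec$name, "'")
  )
  pmin(pmax(x, spec$min), spec$max)
}

#' Generate synthetic site covariates
#'
#' Draws one covariate row per site-year under the marginal specifications.
#' Hydrologic covariates (depth, recession, days-dry) vary independently by
#' site-year; canopy cover and the cell coordinates are drawn once per cell
#' and repeated across years.  Coordinates are snapped to the cell-size
#' lattice.  Deterministic given the design seed.
#'
#' @param design a \linkS4class{surveyDesign}.
#' @param specs covariate specification data.frame as returned by
#'   \code{\link{defaultCovariateSpecs}}.
#' @param seed integer; defaults to the design seed.
#' @return an unstandardized \linkS4class{covariateData} with
#'   \code{nCells * nYears} rows.
#' @examples
#' covs <- generateCovariates(surveyDesign(nCells = 50, nYears = 2))
#' covs
#' @export
generateCovariates <- function(design, specs = defaultCovariateSpecs(),
                               seed = design@seed) {
  stopifnot(is(design, "surveyDesign"))
  req <- c("name", "mean", "sd", "min", "max", "quadratic")
  if (!all(req %in% names(specs)))
    stop("specs must have columns ", paste(req, collapse = ", "))
  if (is.null(specs$dist)) specs$dist <- "tnorm"
  if (anyNA(specs$name) || any(!nzchar(specs$name)) ||
      anyDuplicated(specs$name))
    stop("covariate names must be unique and non-empty")
  perCell <- intersect(specs$name, c("canopy", "easting", "northing"))

  nC <- design@nCells; nY <- design@nYears
  n <- nC * nY
  set.seed(.childSeed(seed, 1L))
  vals <- matrix(NA_real_, n, nrow(specs),
                 dimnames = list(NULL, specs$name))
  for (r in seq_len(nrow(specs))) {
    sp <- specs[r, ]
    if (sp$name %in% perCell) {
      v <- .drawCovariate(sp, nC)
      if (sp$name %in% c("easting", "northing") && sp$sd > 0) {
        v <- round(v / design@cellSize) * design@cellSize
        v <- pmin(pmax(v, sp$min), sp$max)
      }
      vals[, sp$name] <- rep(v, times = nY)
    } else {
      vals[, sp$name] <- .drawCovariate(sp, n)
    }
  }
  cell <- rep(seq_len(nC), times = nY)
  year <- rep(seq_len(nY), each = nC)
  new("covariateData", values = vals,
      siteIds = sprintf("c%04d_y%02d", cell, year),
      year = as.integer(year),
      center = numeric(0), scale = numeric(0), standardized = FALSE)
}

#' Draw species parameters from the community prior
#'
#' Every parameter family (occupancy intercept, each occupancy predictor,
#' detection intercept) receives one value per species.  In
#' \code{"literal"} mode each value is drawn directly from the vague
#' Normal(mu0, 1/tau0) prior.  In \code{"hierarchical"} mode a hypermean
#' and hyper-SD are first drawn per family (from Normal(mu0, 1/tau0) and
#' Uniform(0, sigmaUpper)), or taken from \code{hyperMu} / \code{hyperSigma}
#' when supplied, and species values are drawn around them.
#'
#' @param prior a \linkS4class{communityPrior}.
#' @param nSpecies number of species.
#' @param coefNames occupancy predictor labels.
#' @param seed integer seed.
#' @param hyperMu,hyperSigma optional named vectors over the families
#'   \code{c("alpha_psi", coefNames, "alpha_p")} fixing the community
#'   hyperparameters (hierarchical mode only).
#' @param species optional species labels.
#' @return a \linkS4class{speciesParams}.
#' @export
drawCommunityParams <- function(prior, nSpecies, coefNames, seed = 1L,
                                hyperMu = NULL, hyperSigma = NULL,
                                species = NULL) {
  stopifnot(is(prior, "communityPrior"), nSpecies >= 1)
  if (is.null(species)) {
    dflt <- names(defaultDetectionProbs())
    species <- if (nSpecies <= length(dflt)) dflt[seq_len(nSpecies)] else
      sprintf("sp%02d", seq_len(nSpecies))
  }
  fam <- c("alpha_psi", coefNames, "alpha_p")
  sd0 <- 1 / sqrt(prior@tau0)
  set.seed(.childSeed(seed, 2L))
  if (prior@mode == "literal") {
    vals <- matrix(stats::rnorm(nSpecies * length(fam), prior@mu0, sd0),
                   nSpecies, length(fam), dimnames = list(species, fam))
    hm <- numeric(0); hs <- numeric(0)
  } else {
    hm <- if (is.null(hyperMu))
      stats::setNames(stats::rnorm(length(fam), prior@mu0, sd0), fam) else
      hyperMu[fam]
    hs <- if (is.null(hyperSigma))
      stats::setNames(stats::runif(length(fam), 0, prior@sigmaUpper), fam) else
      hyperSigma[fam]
    if (anyNA(hm) || anyNA(hs))
      stop("hyperMu/hyperSigma must cover families: ",
           paste(fam, collapse = ", "))
    vals <- matrix(stats::rnorm(nSpecies * length(fam)), nSpecies, length(fam),
                   dimnames = list(species, fam))
    vals <- sweep(sweep(vals, 2L, hs, "*"), 2L, hm, "+")
    names(hm) <- names(hs) <- fam
  }
  new("speciesParams",
      alphaPsi = stats::setNames(vals[, "alpha_psi"], species),
      beta = vals[, coefNames, drop = FALSE],
      alphaP = stats::setNames(vals[, "alpha_p"], species),
      coefNames = coefNames, species = species,
      hyperMu = hm, hyperSigma = hs)
}

#' Realistic community parameters for the nine-species wading-bird system
#'
#' A ready-made truth for simulation studies.  Occupancy coefficients are
#' community draws around hypermeans whose signs mirror the fitted system:
#' occupancy peaks at intermediate depths, favours steadily receding water,
#' declines steeply with days dry, increases with canopy cover and trends
#' east and south.  Detection intercepts are fixed at the representative
#' per-visit probabilities of \code{\link{defaultDetectionProbs}} so the
#' community spans common to rarely detected species.
#'
#' @param nSpecies number of species (up to 9 named taxa).
#' @param seed integer seed for the community draws.
#' @param hyperSigma between-species SD shared by all coefficient families.
#' @return a \linkS4class{speciesParams}.
#' @export
exampleCommunityParams <- function(nSpecies = 9L, seed = 1L,
                                   hyperSigma = 0.4) {
  coefNames <- c("depth", "depth_sq", "recession", "recession_sq",
                 "days_dry", "days_dry_sq", "canopy", "easting", "northing")
  hm <- c(alpha_psi = -0.5,
          depth = 0.3, depth_sq = -0.4, recession = 0.3, recession_sq = -0.2,
          days_dry = -1.0, days_dry_sq = -0.2, canopy = 0.5,
          easting = 0.4, northing = -0.5,
          alpha_p = 0)
  hs <- stats::setNames(rep(hyperSigma, length(hm)), names(hm))
  pr <- communityPrior("hierarchical")
  par <- drawCommunityParams(pr, nSpecies, coefNames, seed = seed,
                             hyperMu = hm, hyperSigma = hs)
  pDet <- defaultDetectionProbs()[seq_len(min(nSpecies, 9L))]
  if (nSpecies <= 9L) {
    par@alphaP <- stats::setNames(stats::qlogis(as.numeric(pDet)), par@species)
    par@hyperMu["alpha_p"] <- mean(par@alphaP)
  }
  validObject(par)
  par
}

#' Simulate detection histories under the occupancy model
#'
#' Draws the latent occupancy state z ~ Bernoulli(psi) per site-year and
#' species, then visit-level detections X ~ Bernoulli(p * z); detections can
#' never occur at unoccupied sites.  Optionally masks a fraction of visits
#' missing-at-random.  The latent z and the generating parameters are
#' retained on the returned object for recovery tests.
#'
#' @param params a \linkS4class{speciesParams} (coefficients on the
#'   standardized covariate scale).
#' @param covs a \linkS4class{covariateData}, standardized internally if not
#'   already; NULL for an intercept-only occupancy process.
#' @param design a \linkS4class{surveyDesign} (supplies the visit count).
#' @param seed integer seed.
#' @param pMissing proportion of visits masked NA at random (default 0).
#' @return a \linkS4class{detectionHistory} with latent state attached.
#' @examples
#' des <- surveyDesign(nCells = 100, nYears = 1, nSpecies = 3)
#' par <- exampleCommunityParams(3)
#' covs <- generateCovariates(des)
#' sim <- simulateDetections(par, covs, des, seed = 7)
#' sim
#' @export
simulateDetections <- function(params, covs, design, seed = design@seed,
                               pMissing = 0) {
  stopifnot(is(params, "speciesParams"), is(design, "surveyDesign"))
  if (pMissing < 0 || pMissing >= 1) stop("pMissing must be in [0, 1)")
  if (is.null(covs)) {
    if (length(params@coefNames))
      stop("params have covariate coefficients; supply covs")
    n <- nSites(design)
    X <- matrix(numeric(0), n, 0)
    siteIds <- sprintf("c%04d_y%02d", rep(seq_len(design@nCells), design@nYears),
                       rep(seq_len(design@nYears), each = design@nCells))
    years <- rep(seq_len(design@nYears), each = design@nCells)
  } else {
    stopifnot(is(covs, "covariateData"))
    if (!covs@standardized) covs <- standardizeCovariates(covs)
    X <- buildDesignMatrix(covs, predictors = params@coefNames)
    siteIds <- covs@siteIds
    years <- covs@year
  }
  n <- nrow(X); K <- design@nVisits; I <- length(params@species)
  if (!is.null(covs) && n != nSites(covs))
    stop("design/covariate dimension mismatch")

  eta <- sweep(X %*% t(params@beta), 2L, params@alphaPsi, "+")
  psi <- stats::plogis(eta)                       # n x I
  p <- stats::plogis(params@alphaP)               # length I

  set.seed(.childSeed(seed, 3L))
  z <- matrix(stats::rbinom(n * I, 1L, psi), n, I)
  y <- array(NA_integer_, dim = c(n, K, I),
             dimnames = list(NULL, NULL, params@species))
  for (i in seq_len(I)) {
    det <- matrix(stats::rbinom(n * K, 1L, p[i]), n, K) * z[, i]
    y[, , i] <- det
  }
  if (pMissing > 0) {
    mask <- array(stats::runif(n * K * I) < pMissing, dim = c(n, K, I))
    y[mask] <- NA_integer_
    # a masked visit removes information, not occupancy truth
  }
  colnames(z) <- params@species
  new("detectionHistory", y = y, siteIds = siteIds, years = as.integer(years),
      species = params@species, z = z, trueParams = params)
}
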