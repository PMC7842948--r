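#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Survey design for a stacked multi-season aerial survey
#'
#' Describes the sampling frame of a Systematic-Reconnaissance-Flight style
#' survey: a regular grid of cells, each surveyed on repeat visits within a
#' breeding season, stacked across years.  A "site" is a cell-year; the
#' number of sites is \code{nCells * nYears}.
#'
#' @slot nCells number of grid cells.
#' @slot nYears number of survey years stacked into the site dimension.
#' @slot nVisits number of within-season repeat visits (detection occasions).
#' @slot nSpecies number of species in the community.
#' @slot cellSize grid cell edge length in metres.
#' @slot seed integer seed used by the synthetic generator.
#'
#' @exportClass surveyDesign
setClass("surveyDesign",
  slots = c(
    nCells   = "integer",
    nYears   = "integer",
    nVisits  = "integer",
    nSpecies = "integer",
    cellSize = "numeric",
    seed     = "integer"
  )
)

setValidity("surveyDesign", function(object) {
  counts <- c(object@nCells, object@nYears, object@nVisits, object@nSpecies)
  if (any(is.na(counts)) || any(counts < 1L))
    return("all design counts (nCells, nYears, nVisits, nSpecies) must be >= 1")
  if (object@cellSize <= 0)
    return("cellSize must be positive")
  TRUE
})

#' Construct a survey design
#'
#' Defaults reproduce the Everglades SRF sampling frame analysed by the
#' package's reference workflow: 1,782 grid cells of 2 km, 10 years,
#' 5 monthly visits, and a 9-species wading-bird community, giving
#' \code{1782 * 10 = 17820} site-years.
#'
#' @param nCells,nYears,nVisits,nSpecies,cellSize,seed see
#'   \linkS4class{surveyDesign}.
#' @return a \linkS4class{surveyDesign}.
#' @examples
#' d <- surveyDesign()
#' nSites(d)   # 17820
#' @export
surveyDesign <- function(nCells = 1782L, nYears = 10L, nVisits = 5L,
                         nSpecies = 9L, cellSize = 2000, seed = 1L) {
  new("surveyDesign",
      nCells = as.integer(nCells), nYears = as.integer(nYears),
      nVisits = as.integer(nVisits), nSpecies = as.integer(nSpecies),
      cellSize = as.numeric(cellSize), seed = as.integer(seed))
}

#' Community-level prior on species coefficients
#'
#' The model places a normal prior with mean \code{mu0} and precision
#' \code{tau0} on coefficients.  Two readings are supported:
#' \describe{
#'   \item{\code{"literal"}}{every species-specific coefficient receives the
#'     vague normal prior directly (no cross-species sharing);}
#'   \item{\code{"hierarchical"}}{species coefficients for each predictor are
#'     drawn from a common normal with unknown mean and SD; the hypermean has
#'     the vague normal prior and the hyper-SD a Uniform(0, sigmaUpper)
#'     prior, so rare species borrow strength from the community.}
#' }
#'
#' A third mode, \code{"logistic"}, places a standard logistic prior on
#' every coefficient: for an intercept this is exactly a Uniform(0, 1)
#' prior on the corresponding probability, the conventional vague prior
#' for single-species occupancy fits.  A normal prior with precision 0.001
#' is vague on the logit scale but not on the probability scale -- it
#' concentrates mass near 0 and 1 -- which measurably biases the
#' weakly identified rare-detection regime; see the package vignette.
#'
#' @slot mode "literal", "hierarchical" or "logistic".
#' @slot mu0 prior mean (default 0).
#' @slot tau0 prior precision (default 0.001, i.e. SD about 31.6).
#' @slot sigmaUpper upper bound of the uniform hyper-SD prior.
#' @exportClass communityPrior
setClass("communityPrior",
  slots = c(mode = "character", mu0 = "numeric", tau0 = "numeric",
            sigmaUpper = "numeric")
)

setValidity("communityPrior", function(object) {
  if (!object@mode %in% c("literal", "hierarchical", "logistic"))
    return("mode must be 'literal', 'hierarchical' or 'logistic'")
  if (!is.finite(object@tau0) || object@tau0 <= 0)
    return("tau0 must be a positive precision")
  if (!is.finite(object@sigmaUpper) || object@sigmaUpper <= 0)
    return("sigmaUpper must be positive")
  TRUE
})

#' @rdname communityPrior-class
#' @param mode,mu0,tau0,sigmaUpper see slots.
#' @return a \linkS4class{communityPrior}.
#' @export
communityPrior <- function(mode = c("hierarchical", "literal", "logistic"),
                           mu0 = 0, tau0 = 0.001, sigmaUpper = 10) {
  mode <- match.arg(mode)
  new("communityPrior", mode = mode, mu0 = as.numeric(mu0),
      tau0 = as.numeric(tau0), sigmaUpper = as.numeric(sigmaUpper))
}

#' Site covariates with standardization metadata
#'
#' One row per site-year.  \code{center} and \code{scale} record the
#' natural-unit mean and sample SD used for standardization so that fitted
#' coefficients can be mapped back to natural units.
#'
#' @slot values numeric matrix, sites x covariates, with column names.
#' @slot siteIds site-year identifiers ("cell_year").
#' @slot year survey year of each row.
#' @slot center,scale per-column standardization constants (natural units);
#'   zero-length until \code{\link{standardizeCovariates}} is applied.
#' @slot standardized logical flag.
#' @exportClass covariateData
setClass("covariateData",
  slots = c(values = "matrix", siteIds = "character", year = "integer",
            center = "numeric", scale = "numeric", standardized = "logical")
)

setValidity("covariateData", function(object) {
  if (nrow(object@values) != length(object@siteIds))
    return("values and siteIds disagree on the number of sites")
  if (length(object@year) != length(object@siteIds))
    return("year and siteIds disagree in length")
  if (is.null(colnames(object@values)))
    return("values must have covariate column names")
  if (anyNA(object@values))
    return("covariate values must be complete (no NA)")
  TRUE
})

#' Detection histories for a species community
#'
#' Binary detection/nondetection indexed (site-year, visit, species), with
#' optional missing visits coded NA.  Simulated data retain the latent
#' occupancy state \code{z} and true generating parameters for recovery
#' tests; field data leave them NULL.
#'
#' @slot y integer 3-d array (site x visit x species) in {0, 1, NA}.
#' @slot siteIds,years site-year keys.
#' @slot species species labels.
#' @slot z latent occupancy matrix (site x species) or NULL.
#' @slot trueParams the generating \linkS4class{speciesParams} (as a list
#'   slot) or NULL.
#' @exportClass detectionHistory
setClass("detectionHistory",
  slots = c(y = "array", siteIds = "character", years = "integer",
            species = "character", z = "matrixOrNULL",
            trueParams = "ANY")
)

setValidity("detectionHistory", function(object) {
  d <- dim(object@y)
  if (length(d) != 3L)
    return("y must be a 3-d array (site x visit x species)")
  if (d[1L] != length(object@siteIds)) return("site dimension mismatch")
  if (d[3L] != length(object@species)) return("species dimension mismatch")
  v <- object@y[!is.na(object@y)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("detections must be 0, 1 or NA")
  if (!is.null(object@z)) {
    if (!all(dim(object@z) == d[c(1L, 3L)]))
      return("z must be site x species")
    # a detection at an unoccupied site is impossible
    dcount <- apply(object@y, c(1L, 3L), function(x) sum(x, na.rm = TRUE))
    if (any(dcount > 0 & object@z == 0))
      return("detections present where z == 0")
  }
  TRUE
})

#' Species-level parameters of the occupancy model
#'
#' Occupancy follows logit(psi_ji) = alphaPsi_i + beta_i' x_j on standardized
#' covariates; detection is constant per species, logit(p_i) = alphaP_i.
#'
#' @slot alphaPsi per-species occupancy intercepts (logit scale).
#' @slot beta species x predictor occupancy coefficient matrix (logit scale).
#' @slot alphaP per-species detection intercepts (logit scale).
#' @slot coefNames predictor labels (columns of beta).
#' @slot species species labels.
#' @slot hyperMu,hyperSigma community hypermean / hyper-SD per parameter
#'   family (named; zero-length in literal mode).
#' @exportClass speciesParams
setClass("speciesParams",
  slots = c(alphaPsi = "numeric", beta = "matrix", alphaP = "numeric",
            coefNames = "character", species = "character",
            hyperMu = "numeric", hyperSigma = "numeric")
)

setValidity("speciesParams", function(object) {
  I <- length(object@species)
  if (length(object@alphaPsi) != I || length(object@alphaP) != I)
    return("alphaPsi and alphaP must have one entry per species")
  if (nrow(object@beta) != I || ncol(object@beta) != length(object@coefNames))
    return("beta must be species x coefNames")
  if (!all(is.finite(object@alphaPsi)) || !all(is.finite(object@beta)) ||
      !all(is.finite(object@alphaP)))
    return("parameters must be finite")
  if (length(object@hyperSigma) && any(object@hyperSigma < 0))
    return("hyperSigma must be nonnegative")
  TRUE
})

#' MCMC configuration
#'
#' Defaults follow the reference analysis: 20,000 iterations of 3 chains,
#' 10,000 burn-in, thinning rate 10 (1,000 retained draws per chain).
#'
#' @slot nIter,nBurnin,nChains,thin,seed chain settings.
#' @slot prior a \linkS4class{communityPrior}.
#' @exportClass mcmcConfig
setClass("mcmcConfig",
  slots = c(nIter = "integer", nBurnin = "integer", nChains = "integer",
            thin = "integer", seed = "integer", prior = "communityPrior")
)

setValidity("mcmcConfig", function(object) {
  if (object@nBurnin >= object@nIter)
    return("nBurnin must be smaller than nIter")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@nChains < 2L)
    return("at least 2 chains are required for the R-hat diagnostic")
  TRUE
})

#' @rdname mcmcConfig-class
#' @param nIter,nBurnin,nChains,thin,seed,prior see slots.
#' @return an \linkS4class{mcmcConfig}.
#' @export
mcmcConfig <- function(nIter = 20000L, nBurnin = 10000L, nChains = 3L,
                       thin = 10L, seed = 1L,
                       prior = communityPrior()) {
  new("mcmcConfig", nIter = as.integer(nIter), nBurnin = as.integer(nBurnin),
      nChains = as.integer(nChains), thin = as.integer(thin),
      seed = as.integer(seed), prior = prior)
}

#' Retained posterior draws from an occupancy fit
#'
#' @slot draws numeric 3-d array, chain x retained-draw x parameter, with
#'   parameter dimnames.
#' @slot species,coefNames labels matching the parameter layout.
#' @slot config the \linkS4class{mcmcConfig} used.
#' @slot covInfo list with the training covariates' center, scale and
#'   natural-unit range (used by prediction so scenarios are standardized
#'   with the fit's constants, never re-derived).
#' @exportClass occuPosterior
setClass("occuPosterior",
  slots = c(draws = "array", species = "character", coefNames = "character",
            config = "mcmcConfig", covInfo = "listOrNULL")
)

setValidity("occuPosterior", function(object) {
  if (length(dim(object@draws)) != 3L)
    return("draws must be chain x draw x parameter")
  if (is.null(dimnames(object@draws)[[3L]]))
    return("draws must carry parameter names")
  TRUE
})
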