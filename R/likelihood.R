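#' Standardize site covariates
#'
#' Centers and scales every covariate column to mean 0, SD 1, storing the
#' natural-unit center and scale for back-transformation of response curves
#' and for standardizing scenario covariates with the training constants.
#' The sample-SD convention (denominator n - 1) is used throughout.
#' Applying the function to an already-standardized object is a no-op.
#'
#' @param covs a \linkS4class{covariateData}.
#' @return a standardized \linkS4class{covariateData}.
#' @export
standardizeCovariates <- function(covs) {
  stopifnot(is(covs, "covariateData"))
  if (covs@standardized) return(covs)
  v <- covs@values
  ctr <- colMeans(v)
  scl <- apply(v, 2L, stats::sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad))
    stop("zero-variance covariate column(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  v <- sweep(sweep(v, 2L, ctr, "-"), 2L, scl, "/")
  new("covariateData", values = v, siteIds = covs@siteIds, year = covs@year,
      center = stats::setNames(ctr, colnames(v)),
      scale = stats::setNames(scl, colnames(v)), standardized = TRUE)
}

#' Build the occupancy design matrix
#'
#' Expands standardized covariates into the model's predictor matrix.  The
#' three hydrologic covariates (depth, recession, days-dry) enter both
#' linearly and quadratically; the quadratic column is the square of the
#' standardized linear column (not itself re-standardized), so each response
#' curve stays an interpretable single-variable parabola in natural units.
#' The intercept is implicit (handled by the species intercepts).
#'
#' @param covs a standardized \linkS4class{covariateData}.
#' @param quadratic names of covariates to square; defaults to whichever of
#'   depth, recession and days_dry are present.
#' @param predictors optional explicit predictor layout (e.g. from a
#'   \linkS4class{speciesParams}); names ending in \code{"_sq"} are squares
#'   of the corresponding standardized covariate.
#' @return numeric matrix, sites x predictors, with predictor column names.
#' @export
buildDesignMatrix <- function(covs, quadratic = NULL, predictors = NULL) {
  stopifnot(is(covs, "covariateData"))
  if (!covs@standardized)
    stop("covariates must be standardized before building the design matrix")
  v <- covs@values
  if (!is.null(predictors)) {
    if (!length(predictors))
      return(matrix(numeric(0), nrow(v), 0))
    base <- sub("_sq$", "", predictors)
    miss <- setdiff(base, colnames(v))
    if (length(miss))
      stop("missing required covariate(s): ", paste(miss, collapse = ", "))
    X <- sapply(seq_along(predictors), function(j) {
      col <- v[, base[j]]
      if (grepl("_sq$", predictors[j])) col^2 else col
    })
    X <- matrix(X, nrow = nrow(v), dimnames = list(NULL, predictors))
    return(X)
  }
  if (is.null(quadratic))
    quadratic <- intersect(c("depth", "recession", "days_dry"), colnames(v))
  miss <- setdiff(quadratic, colnames(v))
  if (length(miss))
    stop("missing required covariate(s): ", paste(miss, collapse = ", "))
  cols <- list()
  for (nm in colnames(v)) {
    cols[[nm]] <- v[, nm]
    if (nm %in% quadratic) cols[[paste0(nm, "_sq")]] <- v[, nm]^2
  }
  do.call(cbind, cols)
}

#' Occupancy probability from the logit-linear model
#'
#' psi = inverse-logit(alpha + x' beta), strictly inside (0, 1), saturating
#' smoothly at extreme linear predictors.
#'
#' @param alpha occupancy intercept (logit scale).
#' @param beta predictor coefficient vector.
#' @param x design row (or matrix, sites x predictors).
#' @return occupancy probability (vector if \code{x} is a matrix).
#' @export
occupancyProb <- function(alpha, beta, x) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)))
    stop("parameters must be finite")
  if (is.matrix(x)) stats::plogis(drop(alpha + x %*% beta))
  else stats::plogis(alpha + sum(x * beta))
}

#' Observed-data log-likelihood of one site-species detection history
#'
#' The latent occupancy state is marginalized out:
#' \deqn{L = \psi \prod_k p^{x_k} (1-p)^{1-x_k} + (1-\psi)\,[\mathrm{all}\ x = 0]}
#' Missing visits (NA) are skipped in the product.
#'
#' @param history visit vector in {0, 1, NA}.
#' @param psi,p occupancy and per-visit detection probabilities in [0, 1].
#' @return log-likelihood (scalar).
#' @examples
#' exp(siteSpeciesLoglik(c(1, 0), 0.5, 0.5))   # 0.125
#' exp(siteSpeciesLoglik(c(0, 0), 0.5, 0.5))   # 0.625
#' @export
siteSpeciesLoglik <- function(history, psi, p) {
  if (!is.finite(psi) || psi < 0 || psi > 1)
    stop("psi must be a probability in [0, 1]")
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  obs <- history[!is.na(history)]
  if (length(obs) && !all(obs %in% c(0, 1)))
    stop("history entries must be 0, 1 or NA")
  d <- sum(obs)
  K <- length(obs)
  condDet <- p^d * (1 - p)^(K - d)
  log(psi * condDet + (1 - psi) * (d == 0))
}

# per-site-species detection counts and observed-visit counts
.detCounts <- function(data) {
  y <- data@y
  d <- apply(y, c(1L, 3L), function(x) sum(x, na.rm = TRUE))
  K <- apply(y, c(1L, 3L), function(x) sum(!is.na(x)))
  list(d = d, K = K)
}

#' Total observed-data log-likelihood
#'
#' Sum of \code{\link{siteSpeciesLoglik}} over every site-year and species,
#' with the latent occupancy state marginalized out.  This marginal form is
#' the contract any sampler must agree with (the Gibbs sampler uses data
#' augmentation internally) and the quantity oracle tests enumerate by
#' brute force.
#'
#' @param params a \linkS4class{speciesParams}.
#' @param data a \linkS4class{detectionHistory}.
#' @param X design matrix matching \code{params@coefNames} (see
#'   \code{\link{buildDesignMatrix}}).
#' @return total log-likelihood (scalar).
#' @export
modelLoglik <- function(params, data, X) {
  stopifnot(is(params, "speciesParams"), is(data, "detectionHistory"))
  n <- dim(data@y)[1L]; I <- dim(data@y)[3L]
  if (nrow(X) != n || ncol(X) != length(params@coefNames) ||
      length(params@species) != I)
    stop("shape mismatch between params, data and design matrix")
  cnt <- .detCounts(data)
  psi <- stats::plogis(sweep(X %*% t(params@beta), 2L, params@alphaPsi, "+"))
  p <- stats::plogis(params@alphaP)
  ll <- 0
  for (i in seq_len(I)) {
    condDet <- p[i]^cnt$d[, i] * (1 - p[i])^(cnt$K[, i] - cnt$d[, i])
    lik <- psi[, i] * condDet + (1 - psi[, i]) * (cnt$d[, i] == 0)
    ll <- ll + sum(log(lik))
  }
  ll
}
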