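#' Savage-Dickey log Bayes factor for a point null
#'
#' Evidence that a coefficient differs from zero, computed as the
#' Savage-Dickey density ratio: ln BF10 = ln[prior density at the null /
#' posterior density at the null].  The posterior density at the null is
#' estimated from pooled draws by a Gaussian kernel density with Silverman's
#' bandwidth (\code{method = "kde"}); a normal approximation using the
#' draws' mean and SD is available as a cross-check
#' (\code{method = "normal"}).  A kernel estimate is meaningless beyond the
#' sample range (its tails decay at the bandwidth scale, not the
#' posterior's), so the default \code{method = "auto"} uses the kernel
#' estimate when the null lies inside the range of the draws and the normal
#' tail approximation otherwise; the attribute \code{estimator} records
#' which was used.  A posterior degenerate away from the null returns +Inf
#' with the \code{capped} flag set.
#'
#' ln BF > 4.61 (= ln 100) is decisive evidence for the covariate;
#' ln BF < 0 indicates a covariate with likely negligible effect.
#'
#' @param draws pooled posterior draws of the coefficient (>= 500).
#' @param prior the \linkS4class{communityPrior} under which the
#'   coefficient's marginal prior is Normal(mu0, 1/tau0).
#' @param null the point null (default 0).
#' @param method density estimator at the null.
#' @return numeric ln Bayes factor with attributes \code{decisive},
#'   \code{negligible}, \code{estimator} and \code{capped}.
#' @examples
#' set.seed(1)
#' lnbf <- savageDickeyLnBF(rnorm(5000, 5, 1), communityPrior("literal"))
#' round(lnbf, 1)   # about 9.0
#' @export
savageDickeyLnBF <- function(draws, prior = communityPrior("literal"),
                             null = 0, method = c("auto", "kde", "normal")) {
  method <- match.arg(method)
  stopifnot(is(prior, "communityPrior"))
  draws <- draws[is.finite(draws)]
  if (length(draws) < 500L)
    stop("at least 500 pooled posterior draws are required")
  logPrior <- if (prior@mode == "logistic")
    stats::dlogis(null, prior@mu0, 1, log = TRUE) else
    stats::dnorm(null, prior@mu0, 1 / sqrt(prior@tau0), log = TRUE)
  s <- stats::sd(draws)
  capped <- FALSE
  if (method == "auto")
    method <- if (s > 0 && null >= min(draws) && null <= max(draws))
      "kde" else "normal"
  estimator <- method
  if (s == 0) {
    # degenerate posterior: all mass at a single point
    logPost <- if (all(draws == null)) Inf else -Inf
    estimator <- "degenerate"
    capped <- !all(draws == null)
  } else if (method == "kde") {
    h <- stats::bw.nrd0(draws)
    dens <- mean(stats::dnorm(null, draws, h))
    if (dens > 0) {
      logPost <- log(dens)
    } else {
      logPost <- stats::dnorm(null, mean(draws), s, log = TRUE)
      estimator <- "normal"
      capped <- TRUE
    }
  } else {
    logPost <- stats::dnorm(null, mean(draws), s, log = TRUE)
  }
  lnbf <- logPrior - logPost
  structure(lnbf, decisive = lnbf > 4.61, negligible = lnbf < 0,
            estimator = estimator, capped = capped)
}

#' Species-by-predictor table of Savage-Dickey log Bayes factors
#'
#' @param post an \linkS4class{occuPosterior} with occupancy covariates.
#' @param prior prior used for the density ratio; defaults to the vague
#'   normal component of the fit's prior.
#' @param ... passed to \code{\link{savageDickeyLnBF}}.
#' @return data.frame with columns \code{species, predictor, lnBF,
#'   decisive, negligible}.
#' @export
bayesFactorTable <- function(post, prior = NULL, ...) {
  stopifnot(is(post, "occuPosterior"))
  if (!length(post@coefNames))
    stop("the fit has no occupancy covariates")
  if (is.null(prior)) {
    p0 <- post@config@prior
    prior <- communityPrior("literal", mu0 = p0@mu0, tau0 = p0@tau0)
  }
  grid <- expand.grid(predictor = post@coefNames, species = post@species,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  m <- posteriorDraws(post)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    pn <- sprintf("beta[%s,%s]", grid$predictor[r], grid$species[r])
    savageDickeyLnBF(m[, pn], prior = prior, ...)
  })
  grid$lnBF <- vapply(res, as.numeric, numeric(1L))
  grid$decisive <- vapply(res, attr, logical(1L), "decisive")
  grid$negligible <- vapply(res, attr, logical(1L), "negligible")
  grid
}

#' Dunn-Smyth (randomized quantile) residuals for binary outcomes
#'
#' For outcome y with fitted probability pi, draws u uniformly on
#' (F(y-1), F(y)) with F the Bernoulli CDF (F(-1) = 0, F(0) = 1 - pi,
#' F(1) = 1) and returns the standard-normal quantile of u.  Residuals from
#' a correctly specified model are exactly standard normal.
#'
#' @param observed binary outcome vector.
#' @param fitted fitted probabilities, strictly inside (0, 1).
#' @param seed integer seed for the uniform draws.
#' @param uFrac optional fraction(s) in (0, 1) placing u deterministically
#'   within its interval (0.5 = midpoint); used for oracle checks.
#' @return numeric residual vector.
#' @export
dunnSmythResiduals <- function(observed, fitted, seed = 1L, uFrac = NULL) {
  observed <- as.numeric(observed)
  if (!all(observed %in% c(0, 1)))
    stop("observed outcomes must be binary")
  if (length(fitted) != length(observed))
    stop("observed and fitted lengths differ")
  if (any(!is.finite(fitted)) || any(fitted <= 0) || any(fitted >= 1))
    stop("fitted probabilities must lie strictly inside (0, 1)")
  lo <- ifelse(observed == 1, 1 - fitted, 0)
  hi <- ifelse(observed == 1, 1, 1 - fitted)
  if (is.null(uFrac)) {
    set.seed(seed)
    uFrac <- stats::runif(length(observed))
  }
  stats::qnorm(lo + uFrac * (hi - lo))
}

#' Residuals of an occupancy fit against fitted values
#'
#' Computes per site-year and species the observed ever-detection outcome
#' (detected on at least one visit), the fitted value, and its Dunn-Smyth
#' residual.  The fitted value is by default the ever-detection probability
#' psi * (1 - (1 - p)^K) -- the probability of the observable outcome,
#' against which residual calibration holds -- with plain psi available via
#' \code{type = "psi"}.
#'
#' @param post an \linkS4class{occuPosterior} (posterior-mean parameters are
#'   plugged in).
#' @param data the fitted \linkS4class{detectionHistory}.
#' @param covs covariates used in the fit (NULL for intercept-only).
#' @param type fitted-value convention.
#' @param seed seed for the residual randomization (one draw per
#'   observation).
#' @return data.frame with columns \code{site, species, observed, fitted,
#'   residual}.
#' @export
occuResiduals <- function(post, data, covs = NULL,
                          type = c("ever", "psi"), seed = 1L) {
  type <- match.arg(type)
  fit <- fittedOccupancy(post, data, covs, type = type)
  cnt <- .detCounts(data)
  obs <- (cnt$d > 0) * 1
  res <- dunnSmythResiduals(as.vector(obs), as.vector(fit), seed = seed)
  data.frame(
    site = rep(data@siteIds, times = length(data@species)),
    species = rep(data@species, each = length(data@siteIds)),
    observed = as.vector(obs), fitted = as.vector(fit),
    residual = res, stringsAsFactors = FALSE)
}

#' Fitted occupancy-scale values from posterior means
#'
#' @inheritParams occuResiduals
#' @return sites x species matrix of fitted probabilities.
#' @export
fittedOccupancy <- function(post, data, covs = NULL,
                            type = c("ever", "psi")) {
  type <- match.arg(type)
  stopifnot(is(post, "occuPosterior"), is(data, "detectionHistory"))
  sm <- summarizePosterior(post)
  means <- stats::setNames(sm$mean, sm$param)
  X <- .designFor(post, data, covs)
  I <- length(post@species)
  alphaPsi <- means[sprintf("alpha_psi[%s]", post@species)]
  alphaP <- means[sprintf("alpha_p[%s]", post@species)]
  beta <- matrix(0, I, length(post@coefNames))
  if (length(post@coefNames))
    for (i in seq_len(I))
      beta[i, ] <- means[sprintf("beta[%s,%s]", post@coefNames,
                                 post@species[i])]
  psi <- stats::plogis(sweep(X %*% t(beta), 2L, alphaPsi, "+"))
  if (type == "psi") return(psi)
  K <- .detCounts(data)$K
  p <- stats::plogis(alphaP)
  psi * (1 - sweep(K, 2L, 1 - p, function(k, q) q^k))
}

# design matrix consistent with a fit's predictor layout
.designFor <- function(post, data, covs) {
  n <- dim(data@y)[1L]
  if (!length(post@coefNames)) return(matrix(numeric(0), n, 0))
  if (is.null(covs)) stop("fit used covariates; supply covs")
  if (!covs@standardized) {
    if (!is.null(post@covInfo)) {
      v <- sweep(sweep(covs@values, 2L, post@covInfo$center[colnames(covs@values)], "-"),
                 2L, post@covInfo$scale[colnames(covs@values)], "/")
      covs <- new("covariateData", values = v, siteIds = covs@siteIds,
                  year = covs@year, center = post@covInfo$center,
                  scale = post@covInfo$scale, standardized = TRUE)
    } else covs <- standardizeCovariates(covs)
  }
  buildDesignMatrix(covs, predictors = post@coefNames)
}

#' Residual-versus-fitted adequacy check
#'
#' Least-squares trend of Dunn-Smyth residuals against fitted values, per
#' species.  The model is judged adequate for a species when the 95\%
#' confidence band of the fitted line contains zero across the whole range
#' of fitted values (no systematic trend).
#'
#' @param residual residual vector.
#' @param fitted fitted-value vector.
#' @param species optional grouping vector (one flag per species).
#' @param nGrid evaluation points across the fitted range.
#' @return data.frame with columns \code{species, slope, slopeLo, slopeHi,
#'   adequate}.
#' @export
residualFitCheck <- function(residual, fitted, species = NULL, nGrid = 50L) {
  if (is.null(species)) species <- rep("all", length(residual))
  stopifnot(length(residual) == length(fitted),
            length(species) == length(residual))
  out <- lapply(split(seq_along(residual), species), function(idx) {
    if (length(idx) < 10L)
      stop("at least 10 residuals per species are required")
    df <- data.frame(r = residual[idx], f = fitted[idx])
    fit <- stats::lm(r ~ f, data = df)
    # a residual-free fit (degenerate inputs) is a legitimate case here
    co <- suppressWarnings(summary(fit))$coefficients
    slope <- co["f", "Estimate"]
    se <- co["f", "Std. Error"]
    grid <- data.frame(f = seq(min(df$f), max(df$f), length.out = nGrid))
    pr <- suppressWarnings(
      stats::predict(fit, grid, interval = "confidence", level = 0.95))
    data.frame(slope = slope,
               slopeLo = slope - stats::qt(0.975, fit$df.residual) * se,
               slopeHi = slope + stats::qt(0.975, fit$df.residual) * se,
               adequate = all(pr[, "lwr"] <= 0 & pr[, "upr"] >= 0))
  })
  res <- do.call(rbind, out)
  data.frame(species = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance a randomly chosen
#' detected site receives a higher prediction than a randomly chosen
#' undetected one, ties counted one half.  Computed from midranks.
#'
#' @param observed binary outcome vector (both classes must be present).
#' @param predicted prediction scores.
#' @return AUC in [0, 1].
#' @examples
#' aucOccu(c(1, 0, 1), c(0.9, 0.2, 0.6))   # 1
#' @export
aucOccu <- function(observed, predicted) {
  observed <- as.numeric(observed)
  if (!all(observed %in% c(0, 1))) stop("observed must be binary")
  if (length(observed) != length(predicted)) stop("length mismatch")
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(predicted, ties.method = "average")
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior distribution of species-specific AUC
#'
#' For each retained draw, predicts every site-year from that draw's
#' parameters and scores the prediction against the observed ever-detection
#' outcome; reports the posterior mean and central 95\% interval of AUC per
#' species.
#'
#' @inheritParams occuResiduals
#' @param maxDraws cap on the number of pooled draws scored (evenly
#'   subsampled) to bound cost.
#' @return data.frame with columns \code{species, mean, lo, hi}.
#' @export
aucPosterior <- function(post, data, covs = NULL, type = c("ever", "psi"),
                         maxDraws = 250L) {
  type <- match.arg(type)
  stopifnot(is(post, "occuPosterior"), is(data, "detectionHistory"))
  X <- .designFor(post, data, covs)
  m <- posteriorDraws(post)
  if (nrow(m) > maxDraws)
    m <- m[round(seq(1L, nrow(m), length.out = maxDraws)), , drop = FALSE]
  cnt <- .detCounts(data)
  obs <- (cnt$d > 0) * 1
  I <- length(post@species)
  aucs <- matrix(NA_real_, nrow(m), I, dimnames = list(NULL, post@species))
  for (i in seq_len(I)) {
    sp <- post@species[i]
    aCol <- m[, sprintf("alpha_psi[%s]", sp)]
    pCol <- stats::plogis(m[, sprintf("alpha_p[%s]", sp)])
    bCols <- if (length(post@coefNames))
      m[, sprintf("beta[%s,%s]", post@coefNames, sp), drop = FALSE] else
      matrix(0, nrow(m), 0)
    eta0 <- if (ncol(X)) X %*% t(bCols) else
      matrix(0, nrow(X), nrow(m))
    for (dr in seq_len(nrow(m))) {
      psi <- stats::plogis(eta0[, dr] + aCol[dr])
      pred <- if (type == "ever")
        psi * (1 - (1 - pCol[dr])^cnt$K[, i]) else psi
      aucs[dr, i] <- aucOccu(obs[, i], pred)
    }
  }
  qs <- apply(aucs, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  data.frame(species = post@species, mean = colMeans(aucs),
             lo = qs[1L, ], hi = qs[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}
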