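# numerically stable log(1 + exp(x))
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit the multispecies occupancy model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler for the hierarchical
#' multispecies occupancy model.  Species parameters (occupancy intercept
#' and coefficients, detection intercept) are updated by coordinate-wise
#' random-walk Metropolis against the observed-data likelihood with the
#' latent occupancy state marginalized out (the same quantity
#' \code{\link{modelLoglik}} computes), which mixes far better than
#' conditioning on an imputed z for rarely detected species.  In
#' hierarchical mode each parameter family's community hypermean is drawn
#' from its conjugate normal full conditional and the hyper-SD by
#' random-walk on the log scale under the uniform prior.  The latent state
#' z is still imputed from its Bernoulli full conditional each iteration
#' (forced to 1 wherever the species was detected) so augmented-likelihood
#' diagnostics and z-recovery checks are available.  Proposal scales adapt
#' toward 44\% acceptance during burn-in only, in diminishing batches, and
#' are frozen afterwards.
#'
#' Chains are initialized independently: z at 1 wherever a detection
#' occurred, coefficients from small-variance normal draws, and detection
#' intercepts near the naive detection rate, guaranteeing a finite starting
#' likelihood (with a bounded re-initialization fallback).
#'
#' @param data a \linkS4class{detectionHistory}.
#' @param covs a \linkS4class{covariateData} of occupancy covariates, or
#'   NULL for an intercept-only occupancy model.  Standardized internally
#'   if needed.
#' @param config an \linkS4class{mcmcConfig}; its \code{prior} selects
#'   literal (vague, independent) or hierarchical (community) priors.
#' @param quadratic,predictors passed to \code{\link{buildDesignMatrix}}.
#' @return an \linkS4class{occuPosterior}.  Monitored parameters are
#'   \code{alpha_psi[sp]}, \code{beta[cov,sp]}, \code{alpha_p[sp]}, the
#'   derived per-visit detection probability \code{p[sp]}, and in
#'   hierarchical mode \code{mu[family]} and \code{sigma[family]}.
#' @export
fitOccu <- function(data, covs = NULL, config = mcmcConfig(),
                    quadratic = NULL, predictors = NULL) {
  stopifnot(is(data, "detectionHistory"), is(config, "mcmcConfig"))
  validObject(config)
  I <- length(data@species)
  n <- dim(data@y)[1L]
  covInfo <- NULL
  if (is.null(covs)) {
    X <- matrix(numeric(0), n, 0)
    coefNames <- character(0)
  } else {
    stopifnot(is(covs, "covariateData"))
    raw <- covs
    if (!covs@standardized) covs <- standardizeCovariates(covs)
    X <- buildDesignMatrix(covs, quadratic = quadratic,
                           predictors = predictors)
    coefNames <- colnames(X)
    natural <- if (raw@standardized) NULL else raw@values
    covInfo <- list(
      center = covs@center, scale = covs@scale,
      min = if (is.null(natural)) NULL else apply(natural, 2L, min),
      max = if (is.null(natural)) NULL else apply(natural, 2L, max),
      predictors = coefNames)
  }
  cnt <- .detCounts(data)
  nKeep <- (config@nIter - config@nBurnin) %/% config@thin
  chains <- vector("list", config@nChains)
  for (ch in seq_len(config@nChains)) {
    chains[[ch]] <- .runChain(cnt$d, cnt$K, X, config@prior,
                              config@nIter, config@nBurnin, config@thin,
                              chainSeed = .childSeed(config@seed, 100L + ch),
                              species = data@species, coefNames = coefNames)
  }
  pn <- colnames(chains[[1L]])
  draws <- array(NA_real_, dim = c(config@nChains, nKeep, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(config@nChains)) draws[ch, , ] <- chains[[ch]]
  new("occuPosterior", draws = draws, species = data@species,
      coefNames = coefNames, config = config, covInfo = covInfo)
}

.runChain <- function(d, K, X, prior, nIter, nBurnin, thin, chainSeed,
                      species, coefNames) {
  set.seed(chainSeed)
  n <- nrow(d); I <- ncol(d); P <- ncol(X)
  Xd <- cbind(1, X)                       # intercept + predictors
  hier <- prior@mode == "hierarchical"
  sd0 <- 1 / sqrt(prior@tau0)
  fam <- c("alpha_psi", coefNames, "alpha_p")
  nFam <- P + 2L

  D <- colSums(d)                          # detections per species (fixed)
  anyDet <- d > 0L
  ## coefficient log prior density by mode; logistic = Uniform(0,1) on the
  ## probability for an intercept
  priorLD <- if (prior@mode == "logistic")
    function(x, m, s) stats::dlogis(x, prior@mu0, 1, log = TRUE)
  else
    function(x, m, s) stats::dnorm(x, m, s, log = TRUE)

  init <- function() {
    theta <- matrix(stats::rnorm((P + 1L) * I, 0, 0.1), P + 1L, I)
    naive <- pmin(pmax(D / pmax(colSums(K), 1), 0.01), 0.8)
    alphaP <- stats::qlogis(naive) + stats::rnorm(I, 0, 0.25)
    list(theta = theta, alphaP = alphaP)
  }
  st <- init()
  for (try in 1:10) {
    lp <- Xd %*% st$theta
    if (all(is.finite(lp))) break
    st <- init()
    if (try == 10) stop("could not find a finite starting state")
  }
  theta <- st$theta; alphaP <- st$alphaP
  z <- anyDet * 1L
  hmu <- rep(0, nFam); hsig <- rep(1, nFam)

  sTheta <- matrix(0.3, P + 1L, I); sAlphaP <- rep(0.2, I)
  sHsig <- rep(0.5, nFam)
  accT <- matrix(0L, P + 1L, I); accA <- integer(I); accH <- integer(nFam)
  batchLen <- 50L; batch <- 0L

  pn <- c(sprintf("alpha_psi[%s]", species),
          if (P) as.vector(t(outer(species, coefNames,
                                   function(s, cv) sprintf("beta[%s,%s]", cv, s)))),
          sprintf("alpha_p[%s]", species),
          sprintf("p[%s]", species),
          if (hier) c(sprintf("mu[%s]", fam), sprintf("sigma[%s]", fam)))
  nKeep <- (nIter - nBurnin) %/% thin
  out <- matrix(NA_real_, nKeep, length(pn), dimnames = list(NULL, pn))
  keep <- 0L

  isZero <- !anyDet
  ## per-visit detection term p^d (1-p)^(K-d) for species i at logit p = a
  condDetFor <- function(i, a) exp(d[, i] * a - K[, i] * .softplus(a))
  ## marginal log-likelihood (z integrated out) given the pieces
  margLL <- function(i, lpi, condDet) {
    psi <- stats::plogis(lpi)
    sum(log(psi * condDet + (1 - psi) * isZero[, i]))
  }

  for (it in seq_len(nIter)) {
    ## species parameters against the marginalized likelihood
    for (i in seq_len(I)) {
      a <- alphaP[i]
      condDet <- condDetFor(i, a)
      lpi <- lp[, i]
      lli <- margLL(i, lpi, condDet)
      for (cc in seq_len(P + 1L)) {
        muC <- if (hier) hmu[cc] else prior@mu0
        sdC <- if (hier) hsig[cc] else sd0
        eps <- stats::rnorm(1, 0, sTheta[cc, i])
        lpNew <- lpi + Xd[, cc] * eps
        llNew <- margLL(i, lpNew, condDet)
        cur <- theta[cc, i]
        logr <- llNew - lli +
          priorLD(cur + eps, muC, sdC) - priorLD(cur, muC, sdC)
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          theta[cc, i] <- cur + eps
          lpi <- lpNew; lli <- llNew
          accT[cc, i] <- accT[cc, i] + 1L
        }
      }
      lp[, i] <- lpi
      ## detection intercept, same marginal target
      muC <- if (hier) hmu[nFam] else prior@mu0
      sdC <- if (hier) hsig[nFam] else sd0
      eps <- stats::rnorm(1, 0, sAlphaP[i])
      llB <- margLL(i, lpi, condDetFor(i, a + eps))
      logr <- llB - lli +
        priorLD(a + eps, muC, sdC) - priorLD(a, muC, sdC)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        alphaP[i] <- a + eps
        accA[i] <- accA[i] + 1L
      }
    }
    ## impute the latent occupancy state (diagnostics / recovery checks);
    ## P(z=1 | no detection) = plogis(logit(psi) + K log(1-p))
    pdet <- stats::plogis(alphaP)
    for (i in seq_len(I)) {
      idx <- which(isZero[, i])
      pr <- stats::plogis(lp[idx, i] + K[idx, i] * log1p(-pdet[i]))
      zi <- z[, i]
      zi[idx] <- stats::rbinom(length(idx), 1L, pr)
      z[, i] <- zi
    }
    ## community hyperparameters
    if (hier) {
      allv <- rbind(theta, alphaP)          # nFam x I
      for (f in seq_len(nFam)) {
        v <- allv[f, ]
        prec <- prior@tau0 + I / hsig[f]^2
        m <- (prior@mu0 * prior@tau0 + sum(v) / hsig[f]^2) / prec
        hmu[f] <- stats::rnorm(1, m, 1 / sqrt(prec))
        lsNew <- log(hsig[f]) + stats::rnorm(1, 0, sHsig[f])
        sNew <- exp(lsNew)
        if (sNew < prior@sigmaUpper) {
          S <- sum((v - hmu[f])^2)
          # log full conditional of sigma plus log-scale Jacobian
          lt <- function(s) (1 - I) * log(s) - S / (2 * s^2)
          if (log(stats::runif(1)) < lt(sNew) - lt(hsig[f])) {
            hsig[f] <- sNew
            accH[f] <- accH[f] + 1L
          }
        }
      }
    }
    ## proposal adaptation, burn-in only
    if (it <= nBurnin && it %% batchLen == 0L) {
      batch <- batch + 1L
      delta <- min(0.1, 1 / sqrt(batch))
      sTheta <- sTheta * exp(ifelse(accT / batchLen > 0.44, delta, -delta))
      sAlphaP <- sAlphaP * exp(ifelse(accA / batchLen > 0.44, delta, -delta))
      sHsig <- sHsig * exp(ifelse(accH / batchLen > 0.44, delta, -delta))
      accT[] <- 0L; accA[] <- 0L; accH[] <- 0L
    }
    ## record
    if (it > nBurnin && (it - nBurnin) %% thin == 0L) {
      keep <- keep + 1L
      row <- c(theta[1L, ],
               if (P) as.vector(theta[-1L, , drop = FALSE]),
               alphaP, stats::plogis(alphaP),
               if (hier) c(hmu, hsig))
      out[keep, ] <- row
    }
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Plain Gelman-Rubin PSRF per parameter: with m chains of n retained draws,
#' W the mean within-chain variance and B/n the variance of the chain means,
#' \deqn{\hat{R} = \sqrt{\frac{(n-1)/n\,W + B/n}{W}}.}
#' \code{split = TRUE} halves each chain first (detecting within-chain
#' drift); \code{rankNormalized = TRUE} additionally maps pooled draws to
#' normal scores before splitting.  Values near 1 indicate convergence;
#' the conventional acceptance threshold is 1.1.
#'
#' @param x an \linkS4class{occuPosterior} or a chains x draws x parameters
#'   array (or chains x draws matrix for one parameter).
#' @param split halve chains before computing the statistic.
#' @param rankNormalized rank-normalize draws first (implies split).
#' @return named numeric vector of R-hat values.  Constant parameters give
#'   1; disjoint constant chains give Inf.
#' @export
gelmanRhat <- function(x, split = FALSE, rankNormalized = FALSE) {
  a <- if (is(x, "occuPosterior")) x@draws else x
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3L)
  m <- dim(a)[1L]; n <- dim(a)[2L]
  if (m < 2L) stop("at least 2 chains are required for R-hat")
  if (n < 4L) stop("at least 4 retained draws per chain are required")
  if (rankNormalized) split <- TRUE
  vapply(seq_len(dim(a)[3L]), function(j) {
    ch <- a[, , j, drop = TRUE]
    if (is.null(dim(ch))) ch <- matrix(ch, nrow = m)
    if (rankNormalized) {
      r <- rank(ch, ties.method = "average")
      ch <- matrix(stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4)), nrow = m)
    }
    if (split) {
      half <- n %/% 2L
      ch <- rbind(ch[, seq_len(half), drop = FALSE],
                  ch[, (n - half + 1L):n, drop = FALSE])
    }
    nn <- ncol(ch)
    W <- mean(apply(ch, 1L, stats::var))
    B <- nn * stats::var(rowMeans(ch))
    if (W == 0) return(if (B > 0) Inf else 1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1L), USE.NAMES = FALSE) -> r
  names(r) <- dimnames(a)[[3L]]
  r
}

#' Summarize posterior draws
#'
#' Pooled-chain posterior mean, SD and central 95\% credible interval per
#' parameter, the Gelman-Rubin R-hat, and the importance flag: a predictor
#' is flagged important when its 95\% credible interval excludes zero.
#'
#' @param post an \linkS4class{occuPosterior}.
#' @param probs interval probabilities (default central 95\%).
#' @return data.frame with columns \code{param, mean, sd, lo, hi, rhat,
#'   important}.
#' @export
summarizePosterior <- function(post, probs = c(0.025, 0.975)) {
  stopifnot(is(post, "occuPosterior"))
  m <- posteriorDraws(post)
  qs <- apply(m, 2L, stats::quantile, probs = probs, names = FALSE)
  out <- data.frame(
    param = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    lo = qs[1L, ],
    hi = qs[2L, ],
    rhat = gelmanRhat(post),
    row.names = NULL, stringsAsFactors = FALSE)
  out$important <- out$lo > 0 | out$hi < 0
  out
}
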