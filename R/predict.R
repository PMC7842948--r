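#' Posterior response curve for one covariate
#'
#' Sweeps a covariate across its observed natural-unit range while holding
#' every other model variable at its mean (standardized 0), computing the
#' occupancy probability for every retained draw -- including the
#' covariate's quadratic term when the model has one -- and summarizing to
#' the posterior mean and central 95\% interval.
#'
#' @param post an \linkS4class{occuPosterior} with covariates.
#' @param covariate covariate name (natural scale, e.g. "depth").
#' @param covs the training \linkS4class{covariateData} in natural units
#'   (supplies the observed range); optional if the fit stored ranges.
#' @param nPoints number of grid points.
#' @param species species to evaluate (default all).
#' @return data.frame with columns \code{species, covariate, value, mean,
#'   lo, hi}.
#' @export
responseCurve <- function(post, covariate, covs = NULL, nPoints = 100L,
                          species = NULL) {
  stopifnot(is(post, "occuPosterior"))
  info <- post@covInfo
  if (is.null(info)) stop("the fit has no covariate metadata")
  base <- sub("_sq$", "", post@coefNames)
  if (!covariate %in% base)
    stop("unknown covariate '", covariate, "'; model predictors are built ",
         "from: ", paste(unique(base), collapse = ", "))
  rng <- if (!is.null(covs)) range(covs@values[, covariate]) else
    c(info$min[covariate], info$max[covariate])
  if (anyNA(rng)) stop("no observed range available for '", covariate, "'")
  xNat <- seq(rng[1L], rng[2L], length.out = nPoints)
  xStd <- (xNat - info$center[covariate]) / info$scale[covariate]
  if (is.null(species)) species <- post@species
  m <- posteriorDraws(post)
  linNm <- covariate
  sqNm <- paste0(covariate, "_sq")
  out <- lapply(species, function(sp) {
    a <- m[, sprintf("alpha_psi[%s]", sp)]
    bL <- m[, sprintf("beta[%s,%s]", linNm, sp)]
    bQ <- if (sqNm %in% post@coefNames)
      m[, sprintf("beta[%s,%s]", sqNm, sp)] else rep(0, nrow(m))
    eta <- outer(a, rep(1, nPoints)) + outer(bL, xStd) + outer(bQ, xStd^2)
    psi <- stats::plogis(eta)
    qs <- apply(psi, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    data.frame(species = sp, covariate = covariate, value = xNat,
               mean = colMeans(psi), lo = qs[1L, ], hi = qs[2L, ],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predict a species occupancy map for a covariate scenario
#'
#' Plugs the posterior-mean parameters through the logit link at every grid
#' cell ("plugin", the default, matching the reference map workflow).  The
#' alternative \code{type = "mean"} averages per-draw occupancy
#' probabilities, which differs by Jensen's inequality; the maximum cellwise
#' difference between the two is reported via a message.  Scenario
#' covariates are standardized with the training center/scale stored in the
#' fit -- never re-derived from the scenario -- so coefficients retain their
#' meaning across scenarios; values outside the training range trigger a
#' warning, not an error.
#'
#' @param post an \linkS4class{occuPosterior}.
#' @param covs scenario covariates in natural units
#'   (\linkS4class{covariateData}).
#' @param scenario label stored with the prediction.
#' @param type "plugin" (posterior-mean parameters) or "mean"
#'   (posterior mean of psi).
#' @return data.frame with columns \code{site, easting, northing, species,
#'   psi, scenario}.
#' @export
predictOccupancyMap <- function(post, covs, scenario = "baseline",
                                type = c("plugin", "mean")) {
  type <- match.arg(type)
  stopifnot(is(post, "occuPosterior"), is(covs, "covariateData"))
  info <- post@covInfo
  if (is.null(info)) stop("the fit has no covariate metadata")
  if (covs@standardized)
    stop("scenario covariates must be supplied in natural units")
  nat <- covs@values
  if (!is.null(info$min)) {
    for (nm in intersect(colnames(nat), names(info$min))) {
      if (any(nat[, nm] < info$min[nm] | nat[, nm] > info$max[nm]))
        warning("scenario covariate '", nm,
                "' extends outside the training range", call. = FALSE)
    }
  }
  v <- sweep(sweep(nat, 2L, info$center[colnames(nat)], "-"),
             2L, info$scale[colnames(nat)], "/")
  X <- buildDesignMatrix(
    new("covariateData", values = v, siteIds = covs@siteIds,
        year = covs@year, center = info$center, scale = info$scale,
        standardized = TRUE),
    predictors = post@coefNames)
  I <- length(post@species)
  sm <- summarizePosterior(post)
  means <- stats::setNames(sm$mean, sm$param)
  psi <- matrix(NA_real_, nrow(X), I, dimnames = list(NULL, post@species))
  if (type == "plugin") {
    for (i in seq_len(I)) {
      sp <- post@species[i]
      b <- if (length(post@coefNames))
        means[sprintf("beta[%s,%s]", post@coefNames, sp)] else numeric(0)
      psi[, i] <- occupancyProb(means[sprintf("alpha_psi[%s]", sp)], b, X)
    }
  } else {
    m <- posteriorDraws(post)
    for (i in seq_len(I)) {
      sp <- post@species[i]
      bCols <- if (length(post@coefNames))
        m[, sprintf("beta[%s,%s]", post@coefNames, sp), drop = FALSE] else
        matrix(0, nrow(m), 0)
      eta <- (if (ncol(X)) X %*% t(bCols) else matrix(0, nrow(X), nrow(m))) +
        rep(m[, sprintf("alpha_psi[%s]", sp)], each = nrow(X))
      psi[, i] <- rowMeans(stats::plogis(eta))
    }
  }
  e <- if ("easting" %in% colnames(nat)) nat[, "easting"] else NA_real_
  no <- if ("northing" %in% colnames(nat)) nat[, "northing"] else NA_real_
  data.frame(
    site = rep(covs@siteIds, times = I),
    easting = rep(e, times = I), northing = rep(no, times = I),
    species = rep(post@species, each = nrow(X)),
    psi = as.vector(psi), scenario = scenario, stringsAsFactors = FALSE)
}

#' Percent difference in predicted occupancy between scenarios
#'
#' Cell-by-cell, species-by-species percent difference
#' 100 * (psi_alt - psi_base) / psi_base, the decision metric for comparing
#' a baseline against an alternative hydrologic scenario.  Requires
#' identical cell and species sets.
#'
#' @param baseline,alternative prediction tables from
#'   \code{\link{predictOccupancyMap}}.
#' @return data.frame with columns \code{site, species, psiBase, psiAlt,
#'   pctDiff}; a per-species summary (mean, median, share of cells
#'   improving) is attached as attribute \code{"summary"}.
#' @export
compareScenarios <- function(baseline, alternative) {
  keyB <- paste(baseline$site, baseline$species)
  keyA <- paste(alternative$site, alternative$species)
  if (length(keyB) != length(keyA) || !setequal(keyB, keyA)) {
    off <- union(setdiff(keyB, keyA), setdiff(keyA, keyB))
    stop("scenario grids do not match; offending cells: ",
         paste(utils::head(off, 10L), collapse = "; "),
         if (length(off) > 10L) " ...")
  }
  alternative <- alternative[match(keyB, keyA), ]
  out <- data.frame(
    site = baseline$site, species = baseline$species,
    psiBase = baseline$psi, psiAlt = alternative$psi,
    stringsAsFactors = FALSE)
  out$pctDiff <- ifelse(out$psiBase > 0,
                        100 * (out$psiAlt - out$psiBase) / out$psiBase,
                        NA_real_)
  summ <- do.call(rbind, lapply(split(out, out$species), function(d) {
    data.frame(species = d$species[1L],
               mean = mean(d$pctDiff, na.rm = TRUE),
               median = stats::median(d$pctDiff, na.rm = TRUE),
               shareImproving = mean(d$pctDiff > 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

#' Export one species layer of a prediction as an ESRI ASCII grid
#'
#' Writes a plain-text raster (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header) for GIS use.  Cells sharing a snapped coordinate
#' are averaged; empty lattice positions receive NODATA.
#'
#' @param grid prediction table from \code{\link{predictOccupancyMap}}.
#' @param species species layer to export.
#' @param file output path.
#' @param cellSize lattice spacing in metres.
#' @param nodata NODATA value.
#' @return the file path, invisibly.
#' @export
writeAsciiGrid <- function(grid, species, file, cellSize = 2000,
                           nodata = -9999) {
  g <- grid[grid$species == species, ]
  if (!nrow(g)) stop("species '", species, "' not present in the grid")
  if (anyNA(g$easting) || anyNA(g$northing))
    stop("grid lacks easting/northing coordinates")
  cx <- round(g$easting / cellSize)
  cy <- round(g$northing / cellSize)
  xs <- seq(min(cx), max(cx))
  ys <- seq(max(cy), min(cy))           # rasters are written north to south
  mat <- matrix(nodata, length(ys), length(xs))
  val <- tapply(g$psi, list(cy, cx), mean)
  for (r in rownames(val)) for (cc in colnames(val)) {
    v <- val[r, cc]
    if (!is.na(v))
      mat[match(as.integer(r), ys), match(as.integer(cc), xs)] <- v
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(xs)),
    paste("nrows", length(ys)),
    paste("xllcorner", (min(cx) - 0.5) * cellSize),
    paste("yllcorner", (min(cy) - 0.5) * cellSize),
    paste("cellsize", cellSize),
    paste("NODATA_value", nodata)), con)
  utils::write.table(mat, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
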