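#' Number of site-years in an object
#' @param x a \linkS4class{surveyDesign}, \linkS4class{covariateData} or
#'   \linkS4class{detectionHistory}.
#' @return integer count of site-years.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Species labels carried by an object
#' @param x an object with a species dimension.
#' @return character vector of species codes.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Detection array accessor
#' @param x a \linkS4class{detectionHistory}.
#' @return the (site x visit x species) integer array.
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' Latent occupancy state accessor
#' @param x a \linkS4class{detectionHistory} produced by the simulator.
#' @return site x species 0/1 matrix, or NULL for field data.
#' @export
setGeneric("latentState", function(x) standardGeneric("latentState"))

#' Pooled posterior draws as a matrix
#' @param x an \linkS4class{occuPosterior}.
#' @param param optional parameter name(s) to extract.
#' @return matrix of pooled draws (chains stacked), one column per parameter.
#' @export
setGeneric("posteriorDraws",
           function(x, param = NULL) standardGeneric("posteriorDraws"))

#' @rdname nSites
#' @export
setMethod("nSites", "surveyDesign", function(x) x@nCells * x@nYears)
#' @rdname nSites
#' @export
setMethod("nSites", "covariateData", function(x) nrow(x@values))
#' @rdname nSites
#' @export
setMethod("nSites", "detectionHistory", function(x) dim(x@y)[1L])

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "detectionHistory", function(x) x@species)
#' @rdname speciesNames
#' @export
setMethod("speciesNames", "speciesParams", function(x) x@species)
#' @rdname speciesNames
#' @export
setMethod("speciesNames", "occuPosterior", function(x) x@species)

#' @rdname detections
#' @export
setMethod("detections", "detectionHistory", function(x) x@y)

#' @rdname latentState
#' @export
setMethod("latentState", "detectionHistory", function(x) x@z)

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "occuPosterior", function(x, param = NULL) {
  d <- x@draws
  m <- do.call(rbind, lapply(seq_len(dim(d)[1L]), function(ch) d[ch, , , drop = TRUE]))
  dim(m) <- c(dim(d)[1L] * dim(d)[2L], dim(d)[3L])
  colnames(m) <- dimnames(d)[[3L]]
  if (!is.null(param)) {
    miss <- setdiff(param, colnames(m))
    if (length(miss))
      stop("unknown parameter(s): ", paste(miss, collapse = ", "))
    m <- m[, param, drop = FALSE]
  }
  m
})

setMethod("show", "surveyDesign", function(object) {
  cat("surveyDesign:", object@nCells, "cells x", object@nYears, "years (",
      nSites(object), "site-years ),", object@nVisits, "visits,",
      object@nSpecies, "species, cell", object@cellSize, "m\n")
})

setMethod("show", "communityPrior", function(object) {
  cat("communityPrior:", object@mode, "- Normal(mu0 =", object@mu0,
      ", precision =", object@tau0, ")")
  if (object@mode == "hierarchical")
    cat(", hyper-SD ~ Uniform(0,", object@sigmaUpper, ")")
  cat("\n")
})

setMethod("show", "covariateData", function(object) {
  cat("covariateData:", nrow(object@values), "site-years x",
      ncol(object@values), "covariates (",
      paste(colnames(object@values), collapse = ", "), ")\n")
  cat("  standardized:", object@standardized, "\n")
})

setMethod("show", "detectionHistory", function(object) {
  d <- dim(object@y)
  ndet <- sum(object@y, na.rm = TRUE)
  cat("detectionHistory:", d[1L], "site-years x", d[2L], "visits x", d[3L],
      "species;", ndet, "detections\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  latent state retained:", !is.null(object@z), "\n")
})

setMethod("show", "speciesParams", function(object) {
  cat("speciesParams:", length(object@species), "species,",
      length(object@coefNames), "occupancy predictors\n")
  cat("  per-visit detection p:",
      paste(sprintf("%s=%.3f", object@species, stats::plogis(object@alphaP)),
            collapse = " "), "\n")
})

setMethod("show", "mcmcConfig", function(object) {
  kept <- (object@nIter - object@nBurnin) %/% object@thin
  cat("mcmcConfig:", object@nChains, "chains x", object@nIter, "iterations,",
      object@nBurnin, "burn-in, thin", object@thin,
      "->", kept, "retained draws/chain\n")
  show(object@prior)
})

setMethod("show", "occuPosterior", function(object) {
  d <- dim(object@draws)
  cat("occuPosterior:", d[1L], "chains x", d[2L], "draws x", d[3L],
      "parameters\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
})
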