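#' @importFrom data.table fread fwrite as.data.table data.table :=
NULL

#' Write detection histories as long-format CSV
#'
#' Columns: \code{site_id, year, visit, species, detected} (0/1; missing
#' visits are omitted).  The inverse of \code{\link{readDataset}}.
#'
#' @param data a \linkS4class{detectionHistory}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDetections <- function(data, path) {
  stopifnot(is(data, "detectionHistory"))
  d <- dim(data@y)
  long <- data.table::data.table(
    site_id = rep(data@siteIds, times = d[2L] * d[3L]),
    year = rep(data@years, times = d[2L] * d[3L]),
    visit = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    species = rep(data@species, each = d[1L] * d[2L]),
    detected = as.integer(data@y))
  long <- long[!is.na(long$detected)]
  data.table::fwrite(long, path)
  invisible(path)
}

#' Write site covariates as CSV
#'
#' Columns: \code{site_id, year}, then one column per covariate in natural
#' units.
#'
#' @param covs a \linkS4class{covariateData}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCovariates <- function(covs, path) {
  stopifnot(is(covs, "covariateData"))
  out <- data.table::data.table(site_id = covs@siteIds, year = covs@year)
  out <- cbind(out, data.table::as.data.table(covs@values))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write the simulation truth (latent states and parameters)
#'
#' Persists the latent occupancy matrix and the generating parameters of a
#' simulated dataset for parameter-recovery studies: \code{<stem>_z.csv}
#' (site_id, year, one column per species) and \code{<stem>_params.csv}
#' (species x parameter).
#'
#' @param data a simulated \linkS4class{detectionHistory}.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
writeTruth <- function(data, stem) {
  stopifnot(is(data, "detectionHistory"))
  if (is.null(data@z) || is.null(data@trueParams))
    stop("dataset carries no simulation truth")
  zPath <- paste0(stem, "_z.csv")
  pPath <- paste0(stem, "_params.csv")
  z <- data.table::data.table(site_id = data@siteIds, year = data@years)
  z <- cbind(z, data.table::as.data.table(data@z))
  data.table::fwrite(z, zPath)
  par <- data@trueParams
  tab <- data.table::data.table(species = par@species,
                                alpha_psi = par@alphaPsi,
                                alpha_p = par@alphaP)
  if (length(par@coefNames))
    tab <- cbind(tab, data.table::as.data.table(par@beta))
  data.table::fwrite(tab, pPath)
  invisible(c(zPath, pPath))
}

#' Read a detection/covariate dataset from CSV
#'
#' Loads long-format detections and a covariate table, validates them, and
#' pivots to the package's array containers.  Site-year keys must align
#' exactly between the two files.
#'
#' @param detPath detections CSV (site_id, year, visit, species, detected).
#' @param covPath covariates CSV (site_id, year, covariate columns).
#' @return list with elements \code{data} (\linkS4class{detectionHistory})
#'   and \code{covs} (\linkS4class{covariateData}, natural units).
#' @export
readDataset <- function(detPath, covPath) {
  for (f in c(detPath, covPath))
    if (!file.exists(f)) stop("file not found: ", f)
  det <- data.table::fread(detPath)
  req <- c("site_id", "year", "visit", "species", "detected")
  miss <- setdiff(req, names(det))
  if (length(miss))
    stop("detections file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!det$detected %in% c(0L, 1L))
  if (length(bad))
    stop("non-binary 'detected' values at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...")
  dup <- duplicated(det[, c("site_id", "year", "visit", "species")])
  if (any(dup))
    stop("duplicate (site, year, visit, species) row(s), e.g. row ",
         which(dup)[1L])

  covs <- data.table::fread(covPath)
  if (!all(c("site_id", "year") %in% names(covs)))
    stop("covariates file lacks site_id/year columns")
  keyD <- unique(paste(det$site_id, det$year))
  keyC <- paste(covs$site_id, covs$year)
  if (anyDuplicated(keyC)) stop("duplicate site-year rows in covariates")
  orphan <- c(setdiff(keyD, keyC), setdiff(keyC, keyD))
  if (length(orphan))
    stop("site-year keys unmatched between files: ",
         paste(utils::head(orphan, 10L), collapse = "; "),
         if (length(orphan) > 10L) " ...")

  siteIds <- as.character(covs$site_id)
  years <- as.integer(covs$year)
  species <- unique(det$species)
  visits <- sort(unique(det$visit))
  n <- length(siteIds); K <- length(visits); I <- length(species)
  y <- array(NA_integer_, dim = c(n, K, I),
             dimnames = list(NULL, NULL, species))
  j <- match(paste(det$site_id, det$year), keyC)
  k <- match(det$visit, visits)
  i <- match(det$species, species)
  y[cbind(j, k, i)] <- as.integer(det$detected)

  vmat <- as.matrix(covs[, setdiff(names(covs), c("site_id", "year")),
                         with = FALSE])
  list(
    data = new("detectionHistory", y = y, siteIds = siteIds, years = years,
               species = species, z = NULL, trueParams = NULL),
    covs = new("covariateData", values = vmat, siteIds = siteIds,
               year = years, center = numeric(0), scale = numeric(0),
               standardized = FALSE))
}

#' Persist posterior draws and run metadata
#'
#' Writes \code{draws.csv} (chain, draw, one column per parameter) and
#' \code{meta.json} (species, predictor layout, chain configuration,
#' covariate standardization constants) into a directory.  Inverse of
#' \code{\link{readPosterior}}.
#'
#' @param post an \linkS4class{occuPosterior}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePosterior <- function(post, dir) {
  stopifnot(is(post, "occuPosterior"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(post@draws)
  m <- posteriorDraws(post)
  tab <- data.table::data.table(
    chain = rep(seq_len(d[1L]), each = d[2L]),
    draw = rep(seq_len(d[2L]), times = d[1L]))
  tab <- cbind(tab, data.table::as.data.table(m))
  data.table::fwrite(tab, file.path(dir, "draws.csv"))
  cfg <- post@config
  meta <- list(
    species = post@species, coefNames = post@coefNames,
    config = list(nIter = cfg@nIter, nBurnin = cfg@nBurnin,
                  nChains = cfg@nChains, thin = cfg@thin, seed = cfg@seed,
                  prior = list(mode = cfg@prior@mode, mu0 = cfg@prior@mu0,
                               tau0 = cfg@prior@tau0,
                               sigmaUpper = cfg@prior@sigmaUpper)),
    covInfo = if (is.null(post@covInfo)) NULL else
      lapply(post@covInfo, as.list))   # keep element names through JSON
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Reload a persisted posterior
#'
#' @param dir directory written by \code{\link{writePosterior}}.
#' @return an \linkS4class{occuPosterior}.
#' @export
readPosterior <- function(dir) {
  tab <- data.table::fread(file.path(dir, "draws.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pn <- setdiff(names(tab), c("chain", "draw"))
  nCh <- max(tab$chain); nDr <- max(tab$draw)
  a <- array(NA_real_, dim = c(nCh, nDr, length(pn)),
             dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(nCh)) {
    sub <- tab[tab$chain == ch, ]
    a[ch, , ] <- as.matrix(sub[order(sub$draw), pn, with = FALSE])
  }
  cfgL <- meta$config
  cfg <- mcmcConfig(cfgL$nIter, cfgL$nBurnin, cfgL$nChains, cfgL$thin,
                    cfgL$seed,
                    communityPrior(cfgL$prior$mode, cfgL$prior$mu0,
                                   cfgL$prior$tau0, cfgL$prior$sigmaUpper))
  ci <- meta$covInfo
  if (!is.null(ci)) {
    ci <- lapply(ci, unlist)
    ci$predictors <- as.character(ci$predictors)
  }
  new("occuPosterior", draws = a,
      species = as.character(meta$species),
      coefNames = as.character(meta$coefNames %||% character(0)),
      config = cfg, covInfo = ci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
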