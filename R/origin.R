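#' Origin correlation at a single candidate site
#'
#' Pearson correlation between the great-circle distance from the candidate
#' site to each accepted kernel node and the node's mean unbiased
#' heterozygosity. Under a serial-founder expansion the correlation is
#' negative at the true source.
#'
#' @param lat,lon candidate origin in decimal degrees.
#' @param kdiv kernel-diversity table from [kernelDiversity()].
#' @return weighted Pearson r, or \code{NA} with a warning when fewer than
#'   two kernels have defined diversity or the diversities are constant.
#' @export
siteCorrelation <- function(lat, lon, kdiv) {
  ok <- is.finite(kdiv$h_mean)
  if (sum(ok) < 2) {
    warning("fewer than two kernels with defined diversity")
    return(NA_real_)
  }
  d <- haversineKm(lat, lon, kdiv$lat, kdiv$lon)
  r <- .wPearson(d, kdiv$h_mean, rep(1, nrow(kdiv)))
  if (is.na(r)) warning("zero-variance kernel diversities; r undefined")
  r
}

#' Correlation surface over candidate origins
#'
#' The core origin scan: accept kernels over \code{kernelGrid}, measure each
#' kernel's mean unbiased heterozygosity once, then treat every node of
#' \code{grid} as a potential origin and record the Pearson correlation
#' between distance-to-kernels and kernel diversity. More negative nodes
#' are better-supported origins.
#'
#' @param table a [SampleTable-class].
#' @param grid candidate-origin [GeoGrid-class].
#' @param kernelGrid grid scanned for kernels (defaults to \code{grid},
#'   matching the single-scan design in which kernel and origin searches
#'   share the lattice).
#' @param radiusKm,minSamples kernel acceptance rule (500 km, 5 samples).
#' @param dedupe compute diversity once per distinct member set (exactly
#'   equivalent, just faster).
#' @return an [OriginSurface-class].
#' @export
correlationSurface <- function(table, grid, kernelGrid = grid,
                               radiusKm = 500, minSamples = 5,
                               dedupe = TRUE) {
  kernels <- acceptKernels(table, kernelGrid, radiusKm = radiusKm,
                           minSamples = minSamples, dedupe = dedupe)
  if (nKernels(kernels) < 2)
    stop("origin scan needs at least two accepted kernels; got ",
         nKernels(kernels))
  kdiv <- kernelDiversity(kernels, table)
  nodes <- gridNodes(grid)
  D <- .distMatKm(nodes$lat, nodes$lon, kdiv$lat, kdiv$lon)
  r <- .wPearsonRows(D, kdiv$h_mean, rep(1, nrow(kdiv)))
  nlat <- length(gridLats(grid)); nlon <- length(gridLons(grid))
  rmat <- matrix(r, nrow = nlat, ncol = nlon, byrow = TRUE,
                 dimnames = list(gridLats(grid), gridLons(grid)))
  new("OriginSurface", grid = grid, r = rmat, kernels = kernels)
}

#' @rdname accessors
#' @export
setMethod("surfaceValues", "OriginSurface", function(x) x@r)

#' @describeIn bestOrigin most negative correlation node(s)
#' @export
setMethod("bestOrigin", "OriginSurface", function(x, ...) {
  r <- x@r
  if (all(is.na(r))) stop("surface has no defined correlation values")
  lo <- min(r, na.rm = TRUE)
  idx <- which(r == lo, arr.ind = TRUE)
  data.frame(lat = gridLats(x@grid)[idx[, 1]],
             lon = gridLons(x@grid)[idx[, 2]],
             r = r[idx])
})

setMethod("show", "OriginSurface", function(object) {
  r <- object@r
  def <- sum(!is.na(r))
  cat(sprintf("OriginSurface: %d x %d nodes (%d with defined r)\n",
              nrow(r), ncol(r), def))
  if (def) {
    b <- bestOrigin(object)
    cat(sprintf("  r range: [%.3f, %.3f]; best origin: %.2f N, %.2f E\n",
                min(r, na.rm = TRUE), max(r, na.rm = TRUE),
                b$lat[1], b$lon[1]))
  }
  cat(sprintf("  kernels: %d (radius %g km)\n",
              nKernels(object@kernels), object@kernels@radiusKm))
})

#' Serialise a correlation surface as a node table
#'
#' @param surface an [OriginSurface-class].
#' @param path destination file (TSV: lat, lon, r).
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(surface, path) {
  stopifnot(is(surface, "OriginSurface"))
  nodes <- gridNodes(surface@grid)
  nodes$r <- as.vector(t(surface@r))
  utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Permutation comparison of two candidate origin sites
#'
#' Computes the observed difference in origin correlations,
#' \eqn{\Delta r = r(A) - r(B)}, then builds its null distribution by
#' repeatedly reassigning whole genotype vectors across the fixed sampling
#' coordinates (kernel memberships depend only on coordinates and are
#' computed once), recomputing kernel diversities and \eqn{\Delta r} for
#' each of \code{nPerm} permutations. The two-tailed p value is
#' \eqn{(1 + \#\{|\Delta r_{perm}| \ge |\Delta r_{obs}|\}) / (nPerm + 1)},
#' so ties count as exceedances and p is never zero.
#'
#' @param table a [SampleTable-class].
#' @param siteA,siteB numeric (lat, lon) of the two hypothesised origins.
#' @param grid kernel-scan [GeoGrid-class] (the comparison needs r only at
#'   the two sites, so no full origin scan is run).
#' @param labels character(2) site names used in reports.
#' @param radiusKm,minSamples kernel acceptance rule.
#' @param nPerm number of permutations (study convention 1000).
#' @param seed integer RNG seed; the permutation stream is derived
#'   deterministically from it.
#' @return a [PermutationComparison-class].
#' @export
compareOrigins <- function(table, siteA, siteB, grid,
                           labels = c("siteA", "siteB"), radiusKm = 500,
                           minSamples = 5, nPerm = 1000, seed = 1) {
  stopifnot(is(table, "SampleTable"), length(siteA) == 2,
            length(siteB) == 2)
  geo <- geolocatedSubset(table)
  kernels <- acceptKernels(geo, grid, radiusKm = radiusKm,
                           minSamples = minSamples, dedupe = TRUE)
  if (nKernels(kernels) < 2)
    stop("need at least two accepted kernels for a site comparison")
  kt <- kernelCenters(kernels)
  w <- rep(1, nrow(kt))
  dA <- haversineKm(siteA[1], siteA[2], kt$lat, kt$lon)
  dB <- haversineKm(siteB[1], siteB[2], kt$lat, kt$lon)
  enc <- .alleleIndicator(geo)
  # diversity is computed once per distinct member set, then expanded to
  # the accepted nodes
  Mem <- .membershipMatrix(kernels@members, sampleIDs(geo))
  hOf <- function(perm) {
    C <- Matrix::crossprod(enc$X[perm, , drop = FALSE], Mem)
    .hFromCounts(C, enc$Lmap)$hMean[kt$set]
  }
  n <- nSamples(geo)
  hObs <- hOf(seq_len(n))
  rA <- .wPearson(dA, hObs, w)
  rB <- .wPearson(dB, hObs, w)
  if (is.na(rA)) stop("origin correlation undefined at site '",
                      labels[1], "'")
  if (is.na(rB)) stop("origin correlation undefined at site '",
                      labels[2], "'")
  dObs <- rA - rB
  seed <- as.integer(seed)
  set.seed(seed)
  nPerm <- as.integer(nPerm)
  nullD <- vapply(seq_len(nPerm), function(i) {
    perm <- sample.int(n)
    h <- hOf(perm)
    .wPearson(dA, h, w) - .wPearson(dB, h, w)
  }, numeric(1))
  ## undefined permuted r (constant diversity under shuffle) is treated as
  ## an exceedance: conservative
  exceed <- is.na(nullD) | abs(nullD) >= abs(dObs)
  p <- (1 + sum(exceed)) / (nPerm + 1)
  new("PermutationComparison", siteA = as.numeric(siteA),
      siteB = as.numeric(siteB), labels = as.character(labels),
      rA = rA, rB = rB, observedDeltaR = dObs, nullDeltaR = nullD,
      nPerm = nPerm, pTwoTailed = p, seed = seed)
}

#' @rdname accessors
#' @export
setMethod("pValue", "PermutationComparison", function(x) x@pTwoTailed)

#' @rdname accessors
#' @export
setMethod("observedDeltaR", "PermutationComparison",
          function(x) x@observedDeltaR)

#' @rdname accessors
#' @export
setMethod("nullDeltaR", "PermutationComparison", function(x) x@nullDeltaR)

setMethod("show", "PermutationComparison", function(object) {
  cat(sprintf("PermutationComparison: %s vs %s\n",
              object@labels[1], object@labels[2]))
  cat(sprintf("  r(%s) = %.4f, r(%s) = %.4f, delta r = %.4f\n",
              object@labels[1], object@rA, object@labels[2], object@rB,
              object@observedDeltaR))
  cat(sprintf("  two-tailed p = %.4g (%d permutations, seed %d)\n",
              object@pTwoTailed, object@nPerm, object@seed))
})

#' JSON report for a site comparison
#'
#' @param cmp a [PermutationComparison-class].
#' @param path destination file, or \code{NULL} to return the JSON string.
#' @return the JSON text, invisibly when written to \code{path}.
#' @export
comparisonReport <- function(cmp, path = NULL) {
  stopifnot(is(cmp, "PermutationComparison"))
  qs <- stats::quantile(abs(cmp@nullDeltaR), c(0.5, 0.95, 0.99),
                        na.rm = TRUE)
  rep <- list(
    sites = list(
      list(label = cmp@labels[1], lat = cmp@siteA[1], lon = cmp@siteA[2],
           r = cmp@rA),
      list(label = cmp@labels[2], lat = cmp@siteB[1], lon = cmp@siteB[2],
           r = cmp@rB)),
    observed_delta_r = cmp@observedDeltaR,
    n_perm = cmp@nPerm, seed = cmp@seed,
    p_two_tailed = cmp@pTwoTailed,
    null_abs_delta_r = list(median = unname(qs[1]), q95 = unname(qs[2]),
                            q99 = unname(qs[3])))
  json <- .toJSON(rep)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

## minimal JSON serialiser for scalar/list reports (no external dependency)
.toJSON <- function(x) {
  if (is.list(x) && is.null(names(x)))
    return(paste0("[", paste(vapply(x, .toJSON, character(1)),
                             collapse = ","), "]"))
  if (is.list(x))
    return(paste0("{", paste(sprintf("\"%s\":%s", names(x),
                                     vapply(x, .toJSON, character(1))),
                             collapse = ","), "}"))
  if (is.character(x)) return(sprintf("\"%s\"", x))
  if (length(x) > 1)
    return(paste0("[", paste(vapply(x, .toJSON, character(1)),
                             collapse = ","), "]"))
  if (is.na(x)) return("null")
  format(x, digits = 15)
}

#' Bilinear upsampling of a correlation surface (display only)
#'
#' Refines the surface lattice by an integer factor with bilinear
#' interpolation; the refined field agrees exactly with the original values
#' at the original nodes. Interpolation is for map rendering only and never
#' feeds back into any statistic.
#'
#' @param surface an [OriginSurface-class] with at least 2 nodes per axis.
#' @param factor integer >= 1 upsampling ratio (1 returns an identical
#'   surface).
#' @return an [OriginSurface-class] on the refined grid.
#' @export
interpolateSurface <- function(surface, factor) {
  stopifnot(is(surface, "OriginSurface"))
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(surface)
  g <- surface@grid
  lats <- gridLats(g); lons <- gridLons(g)
  if (length(lats) < 2 || length(lons) < 2)
    stop("surface too small to interpolate")
  newRes <- g@resolution / factor
  newLats <- seq(lats[1], lats[length(lats)], by = newRes)
  newLons <- seq(lons[1], lons[length(lons)], by = newRes)
  pts <- expand.grid(lon = newLons, lat = newLats)
  z <- pracma::interp2(x = lons, y = lats, Z = surface@r,
                       xp = pts$lon, yp = pts$lat, method = "linear")
  rmat <- matrix(z, nrow = length(newLats), ncol = length(newLons),
                 byrow = TRUE, dimnames = list(newLats, newLons))
  newGrid <- new("GeoGrid", latMin = lats[1], latMax = lats[length(lats)],
                 lonMin = lons[1], lonMax = lons[length(lons)],
                 resolution = newRes)
  new("OriginSurface", grid = newGrid, r = rmat,
      kernels = surface@kernels)
}
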