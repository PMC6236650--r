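.EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km. Vectorised
#' with the usual recycling rules. Ellipsoidal corrections (< 0.5%) are
#' immaterial at the 500-km kernel scale this package works at, so no
#' projection or datum handling is attempted.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distances in km, symmetric and non-negative.
#' @examples
#' haversineKm(0, 0, 0, 180)  # half the circumference, ~20015 km
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
}

## Full distance matrix (length(lat1) x length(lat2)) in km.
.distMatKm <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  l1 <- lon1 * pi / 180; l2 <- lon2 * pi / 180
  a <- outer(p1, p2, function(x, y) sin((y - x) / 2)^2) +
    (cos(p1) %o% cos(p2)) * outer(l1, l2, function(x, y) sin((y - x) / 2)^2)
  a <- sqrt(a)
  a[a > 1] <- 1
  2 * .EARTH_RADIUS_KM * asin(a)
}

#' Build a regular latitude/longitude grid
#'
#' Nodes are lattice points at \code{min + k * resolution}, inclusive of the
#' lower bound and never exceeding the upper bound (node-registered, not
#' cell-centred).
#'
#' @param latRange,lonRange numeric length-2 bounds in decimal degrees.
#' @param resolution node spacing in degrees (> 0).
#' @return a [GeoGrid-class].
#' @examples
#' gridNodes(buildGrid(c(0, 1), c(0, 1), 0.5))  # 3 x 3 = 9 nodes
#' @export
buildGrid <- function(latRange, lonRange, resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number")
  new("GeoGrid", latMin = latRange[1], latMax = latRange[2],
      lonMin = lonRange[1], lonMax = lonRange[2],
      resolution = as.numeric(resolution))
}

.axisSeq <- function(from, to, by) {
  n <- floor((to - from) / by + 1e-9)
  from + by * (0:n)
}

#' @rdname accessors
#' @export
setMethod("gridLats", "GeoGrid", function(x)
  .axisSeq(x@latMin, x@latMax, x@resolution))

#' @rdname accessors
#' @export
setMethod("gridLons", "GeoGrid", function(x)
  .axisSeq(x@lonMin, x@lonMax, x@resolution))

#' @rdname accessors
#' @export
setMethod("gridNodes", "GeoGrid", function(x) {
  lats <- gridLats(x); lons <- gridLons(x)
  data.frame(lat = rep(lats, each = length(lons)),
             lon = rep(lons, times = length(lats)))
})

setMethod("show", "GeoGrid", function(object) {
  cat(sprintf(
    "GeoGrid: %g..%g N x %g..%g E at %g deg (%d x %d = %d nodes)\n",
    object@latMin, object@latMax, object@lonMin, object@lonMax,
    object@resolution, length(gridLats(object)), length(gridLons(object)),
    length(gridLats(object)) * length(gridLons(object))))
})

#' Accept sample kernels over a grid
#'
#' Scans every grid node and accepts those whose great-circle disc of radius
#' \code{radiusKm} contains at least \code{minSamples} geolocated samples
#' (boundary inclusive: distance <= radius). Local diversity is measured
#' only at accepted kernels. With \code{dedupe = TRUE} the member sets are
#' stored once per distinct set (neighbouring nodes usually trap the same
#' samples), so diversity — the expensive part of permutation testing — is
#' computed once per set; every node keeps its own centre and distances,
#' and results are bit-identical to the non-deduplicated scan.
#'
#' @param table a [SampleTable-class]; non-geolocated records are ignored.
#' @param grid a [GeoGrid-class] to scan.
#' @param radiusKm kernel radius (default 500 km).
#' @param minSamples acceptance threshold (default 5 samples).
#' @param dedupe store one member set per distinct set (default TRUE).
#' @param chunkSize nodes per distance-matrix block, bounding memory use.
#' @return a [KernelSet-class]; empty (with a warning) when no node
#'   qualifies or no sample is geolocated.
#' @export
acceptKernels <- function(table, grid, radiusKm = 500, minSamples = 5,
                          dedupe = TRUE, chunkSize = 20000L) {
  stopifnot(is(table, "SampleTable"), is(grid, "GeoGrid"))
  geo <- geolocatedSubset(table)
  nodes <- gridNodes(grid)
  minSamples <- as.integer(minSamples)
  emptyKS <- function() new("KernelSet",
    kernelTable = data.frame(lat = numeric(0), lon = numeric(0),
                             n_members = integer(0), set = integer(0)),
    members = list(), radiusKm = radiusKm, minSamples = minSamples,
    grid = grid, deduplicated = dedupe)
  if (nSamples(geo) == 0L) {
    warning("no geolocated samples; returning empty KernelSet")
    return(emptyKS())
  }
  co <- coordinates(geo)
  ids <- sampleIDs(geo)
  keyList <- character(0); lat <- numeric(0); lon <- numeric(0)
  nm <- integer(0); mem <- list()
  for (start in seq(1L, nrow(nodes), by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, nrow(nodes))
    D <- .distMatKm(nodes$lat[idx], nodes$lon[idx],
                    co$latitude, co$longitude)
    inside <- D <= radiusKm
    counts <- rowSums(inside)
    hit <- which(counts >= minSamples)
    for (h in hit) {
      members <- which(inside[h, ])
      lat <- c(lat, nodes$lat[idx[h]])
      lon <- c(lon, nodes$lon[idx[h]])
      nm <- c(nm, length(members))
      mem[[length(mem) + 1L]] <- ids[members]
      keyList <- c(keyList, paste(members, collapse = ","))
    }
  }
  if (!length(mem)) {
    warning("no grid node meets the kernel rule; returning empty KernelSet")
    return(emptyKS())
  }
  if (dedupe) {
    set <- match(keyList, unique(keyList))
    mem <- mem[!duplicated(keyList)]
  } else {
    set <- seq_along(mem)
  }
  new("KernelSet",
      kernelTable = data.frame(lat = lat, lon = lon, n_members = nm,
                               set = set),
      members = mem, radiusKm = radiusKm, minSamples = minSamples,
      grid = grid, deduplicated = dedupe)
}

#' @rdname accessors
#' @export
setMethod("nKernels", "KernelSet", function(x) nrow(x@kernelTable))

#' @rdname accessors
#' @export
setMethod("kernelCenters", "KernelSet", function(x) x@kernelTable)

#' @rdname accessors
#' @export
setMethod("kernelMembers", "KernelSet",
          function(x) x@members[x@kernelTable$set])

setMethod("show", "KernelSet", function(object) {
  kt <- object@kernelTable
  cat(sprintf(
    "KernelSet: %d accepted kernel(s) (radius %g km, >= %d samples%s)\n",
    nrow(kt), object@radiusKm, object@minSamples,
    if (object@deduplicated) ", deduplicated" else ""))
  if (nrow(kt))
    cat(sprintf("  members per kernel: %d..%d; distinct member sets: %d\n",
                min(kt$n_members), max(kt$n_members),
                length(object@members)))
})

#' Serialise accepted kernels to delimited text
#'
#' One row per kernel: node coordinates, member count, multiplicity and the
#' semicolon-joined member sample ids; the acceptance rule is written as
#' leading comment lines.
#'
#' @param kernels a [KernelSet-class].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeKernels <- function(kernels, path) {
  stopifnot(is(kernels, "KernelSet"))
  kt <- kernelCenters(kernels)
  kt$member_ids <- vapply(kernelMembers(kernels), paste,
                          character(1), collapse = ";")
  hdr <- sprintf("# radius_km=%g min_samples=%d resolution=%g dedupe=%s",
                 kernels@radiusKm, kernels@minSamples,
                 kernels@grid@resolution, kernels@deduplicated)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(kt, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
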