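#' @import methods
#' @importFrom stats cor prcomp sd var quantile setNames runif
#' @importFrom utils read.table write.table head
NULL

.GBSSI_S_LEVELS <- c("S0/S0", "S0/S-15", "S-15/S-15")
.GBSSI_L_LEVELS <- c("LC/LC", "LY/LY", "Lf/Lf", "LC/LY", "LC/Lf", "LY/Lf")

#' Georeferenced multilocus sample table
#'
#' Container for a set of georeferenced accessions genotyped at L
#' multiallelic loci (typically microsatellites), with optional genotypes at
#' the two duplicated granule-bound starch synthase I loci (GBSSI-S and
#' GBSSI-L) that control the waxy endosperm phenotype.
#'
#' @slot samples data.frame with one row per accession: \code{sample_id},
#'   \code{region}, \code{latitude}, \code{longitude} (decimal degrees, WGS84
#'   spherical interpretation; \code{NA} when unknown), \code{gbssi_s},
#'   \code{gbssi_l}, plus any extra metadata columns carried through I/O
#'   untouched.
#' @slot genotypes character matrix (samples x loci). Each cell holds the
#'   allele call(s) for one sample at one locus: a single label when one copy
#'   is scored per sample, or \code{copies} labels joined by \code{"/"}.
#'   \code{NA} marks a missing call. Allele labels are usually repeat-length
#'   integers but any label is accepted.
#' @slot copies integer, number of allele copies scored per sample per locus
#'   (P). Defaults to 1: broomcorn millet and similar strong selfers are
#'   conventionally scored as a single allele per locus.
#'
#' @seealso [readSamples()], [writeSamples()], [geolocatedSubset()]
#' @export
setClass("SampleTable",
  representation(
    samples   = "data.frame",
    genotypes = "matrix",
    copies    = "integer"
  ),
  prototype(copies = 1L)
)

setValidity("SampleTable", function(object) {
  s <- object@samples
  g <- object@genotypes
  msgs <- character()
  need <- c("sample_id", "region", "latitude", "longitude",
            "gbssi_s", "gbssi_l")
  miss <- setdiff(need, names(s))
  if (length(miss))
    msgs <- c(msgs, paste("samples lacks column(s):",
                          paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(s$sample_id))
      msgs <- c(msgs, "duplicate sample_id values")
    bad <- which(!is.na(s$latitude) & (s$latitude < -90 | s$latitude > 90))
    if (length(bad))
      msgs <- c(msgs, paste0("latitude out of [-90, 90] for row(s) ",
                             paste(head(bad, 5), collapse = ", ")))
    bad <- which(!is.na(s$longitude) &
                   (s$longitude < -180 | s$longitude > 180))
    if (length(bad))
      msgs <- c(msgs, paste0("longitude out of [-180, 180] for row(s) ",
                             paste(head(bad, 5), collapse = ", ")))
    if (nrow(g) != nrow(s))
      msgs <- c(msgs, "genotype matrix rows != sample rows")
    if (is.null(colnames(g)))
      msgs <- c(msgs, "genotype matrix must carry locus names")
    okS <- is.na(s$gbssi_s) | s$gbssi_s %in% .GBSSI_S_LEVELS
    if (!all(okS))
      msgs <- c(msgs, "invalid gbssi_s genotype(s)")
    okL <- is.na(s$gbssi_l) | s$gbssi_l %in% .GBSSI_L_LEVELS
    if (!all(okL))
      msgs <- c(msgs, "invalid gbssi_l genotype(s)")
    P <- object@copies
    if (length(P) != 1L || is.na(P) || P < 1L)
      msgs <- c(msgs, "copies must be a single positive integer")
    else if (length(g) && any(!is.na(g))) {
      nn <- lengths(strsplit(g[!is.na(g)], "/", fixed = TRUE))
      if (any(nn > P))
        msgs <- c(msgs, "a genotype cell holds more calls than `copies`")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Regular latitude/longitude grid
#'
#' A node-registered lattice: nodes sit at the lower bound plus integer
#' multiples of the resolution, inclusive of the lower bound and never
#' exceeding the upper bound on either axis.
#'
#' @slot latMin,latMax,lonMin,lonMax numeric bounds in decimal degrees.
#' @slot resolution numeric node spacing in degrees (> 0).
#' @export
setClass("GeoGrid",
  representation(latMin = "numeric", latMax = "numeric",
                 lonMin = "numeric", lonMax = "numeric",
                 resolution = "numeric"))

setValidity("GeoGrid", function(object) {
  msgs <- character()
  if (object@latMin > object@latMax || object@lonMin > object@lonMax)
    msgs <- c(msgs, "grid bounds must satisfy min <= max")
  if (object@resolution <= 0)
    msgs <- c(msgs, "resolution must be > 0")
  if (object@latMin < -90 || object@latMax > 90 ||
      object@lonMin < -180 || object@lonMax > 180)
    msgs <- c(msgs, "grid bounds out of geographic range")
  if (length(msgs)) msgs else TRUE
})

#' Accepted sample kernels on a grid
#'
#' The grid nodes at which local diversity can be measured: every node whose
#' great-circle disc of radius \code{radiusKm} contains at least
#' \code{minSamples} geolocated samples (boundary inclusive). Neighbouring
#' nodes often trap exactly the same samples; diversity then only needs to
#' be computed once per distinct member set, so the member sets can be
#' stored deduplicated while every accepted node keeps its own centre (and
#' hence its own distances). Deduplication therefore never changes any
#' downstream correlation.
#'
#' @slot kernelTable data.frame with one row per accepted node:
#'   \code{lat}, \code{lon} of the node, \code{n_members}, \code{set}
#'   (index into \code{members}).
#' @slot members list of character vectors of member sample_ids — one per
#'   distinct member set when deduplicated, else one per node.
#' @slot radiusKm,minSamples acceptance rule parameters (defaults 500 km,
#'   5 samples).
#' @slot grid the [GeoGrid-class] searched.
#' @slot deduplicated logical flag: were identical member sets merged.
#' @export
setClass("KernelSet",
  representation(kernelTable = "data.frame", members = "list",
                 radiusKm = "numeric", minSamples = "integer",
                 grid = "GeoGrid", deduplicated = "logical"))

setValidity("KernelSet", function(object) {
  msgs <- character()
  kt <- object@kernelTable
  if (nrow(kt) && !all(c("lat", "lon", "n_members", "set") %in% names(kt)))
    msgs <- c(msgs, "kernelTable lacks required columns")
  else if (nrow(kt)) {
    if (any(kt$set < 1 | kt$set > length(object@members)))
      msgs <- c(msgs, "set index out of range of the member-set list")
    if (any(kt$n_members < object@minSamples))
      msgs <- c(msgs, "kernel below the minimum sample count")
  }
  if (length(msgs)) msgs else TRUE
})

#' Origin-correlation surface
#'
#' Per-grid-node Pearson correlation between great-circle distance from the
#' node to each accepted kernel and the kernel's mean unbiased
#' heterozygosity. More negative values mark more plausible origins of a
#' serial-founder expansion, since diversity is expected to decline with
#' distance from the source.
#'
#' @slot grid the candidate-origin [GeoGrid-class].
#' @slot r numeric matrix (length(gridLats) x length(gridLons)) of
#'   correlations in [-1, 1]; \code{NA} where undefined.
#' @slot kernels the [KernelSet-class] the surface was computed against.
#' @export
setClass("OriginSurface",
  representation(grid = "GeoGrid", r = "matrix", kernels = "KernelSet"))

setValidity("OriginSurface", function(object) {
  r <- object@r
  nlat <- length(gridLats(object@grid))
  nlon <- length(gridLons(object@grid))
  msgs <- character()
  if (!all(dim(r) == c(nlat, nlon)))
    msgs <- c(msgs, "r matrix dimensions do not match grid")
  vals <- r[!is.na(r)]
  if (length(vals) && any(vals < -1 - 1e-9 | vals > 1 + 1e-9))
    msgs <- c(msgs, "correlation values outside [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Permutation comparison of two candidate origin sites
#'
#' Holds the observed difference in origin correlations between two
#' hypothesised origin sites, the permutation null distribution of that
#' difference obtained by reassigning genotype vectors over the fixed
#' sampling locations, and the resulting two-tailed p value.
#'
#' @slot siteA,siteB numeric length-2 (lat, lon) of the candidate sites.
#' @slot labels character length-2 site names.
#' @slot rA,rB observed origin correlations at the two sites.
#' @slot observedDeltaR rA - rB.
#' @slot nullDeltaR numeric vector of permuted differences (length nPerm).
#' @slot nPerm number of permutations (study convention: 1000).
#' @slot pTwoTailed two-tailed p with the +1/(n+1) correction, so p > 0.
#' @slot seed RNG seed used for the permutation stream.
#' @export
setClass("PermutationComparison",
  representation(siteA = "numeric", siteB = "numeric", labels = "character",
                 rA = "numeric", rB = "numeric", observedDeltaR = "numeric",
                 nullDeltaR = "numeric", nPerm = "integer",
                 pTwoTailed = "numeric", seed = "integer"))

setValidity("PermutationComparison", function(object) {
  msgs <- character()
  if (length(object@nullDeltaR) != object@nPerm)
    msgs <- c(msgs, "null distribution length != nPerm")
  if (object@pTwoTailed <= 0 || object@pTwoTailed > 1)
    msgs <- c(msgs, "p must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Serial-founder expansion simulator configuration
#'
#' Parameters of the generative model used to test the pipeline: a radial
#' colonisation of a deme lattice from an origin, each new deme founded by a
#' small bottleneck drawn from its parent and then grown to carrying
#' capacity under Wright-Fisher drift with stepwise microsatellite mutation.
#' This produces the monotonic decline of expected heterozygosity with
#' distance from the origin that the origin scan assumes.
#'
#' @slot origin numeric (lat, lon) of the expansion source.
#' @slot latRange,lonRange numeric length-2 domain bounds (degrees).
#' @slot demeStep lattice spacing in degrees.
#' @slot founderCopies allele copies founding each new deme (bottleneck).
#' @slot demeCapacity allele copies per deme at carrying capacity.
#' @slot generationsPerStep Wright-Fisher generations between colonisation
#'   steps.
#' @slot mutationRate per-copy per-generation probability of a +/-1
#'   repeat-unit stepwise mutation (reflecting bounds).
#' @slot nLoci number of unlinked microsatellite loci (default 16).
#' @slot alleleRange integer length-2 admissible repeat-length range.
#' @slot nSamples accessions sampled from the colonised lattice.
#' @slot sampling "uniform" over demes or "clustered".
#' @slot missingRate per-call missing-data probability.
#' @slot jitterDeg within-deme coordinate jitter (degrees; 0 = samples sit
#'   exactly at deme centres).
#' @slot seed RNG seed; the whole simulation is deterministic given it.
#' @export
setClass("ExpansionConfig",
  representation(origin = "numeric", latRange = "numeric",
                 lonRange = "numeric", demeStep = "numeric",
                 founderCopies = "integer", demeCapacity = "integer",
                 generationsPerStep = "integer", mutationRate = "numeric",
                 nLoci = "integer", alleleRange = "integer",
                 nSamples = "integer", sampling = "character",
                 missingRate = "numeric", jitterDeg = "numeric",
                 seed = "integer"))

setValidity("ExpansionConfig", function(object) {
  msgs <- character()
  if (object@founderCopies > object@demeCapacity)
    msgs <- c(msgs, "founderCopies must not exceed demeCapacity")
  if (object@founderCopies < 1L)
    msgs <- c(msgs, "founderCopies must be >= 1")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msgs <- c(msgs, "mutationRate must lie in [0, 1]")
  if (object@missingRate < 0 || object@missingRate > 1)
    msgs <- c(msgs, "missingRate must lie in [0, 1]")
  if (object@nLoci < 1L)
    msgs <- c(msgs, "nLoci must be >= 1")
  if (diff(object@latRange) < 0 || diff(object@lonRange) < 0)
    msgs <- c(msgs, "domain ranges must be non-decreasing")
  if (object@origin[1] < object@latRange[1] ||
      object@origin[1] > object@latRange[2] ||
      object@origin[2] < object@lonRange[1] ||
      object@origin[2] > object@lonRange[2])
    msgs <- c(msgs, "origin must lie inside the domain")
  if (!object@sampling %in% c("uniform", "clustered"))
    msgs <- c(msgs, "sampling must be 'uniform' or 'clustered'")
  if (length(msgs)) msgs else TRUE
})

#' Simulation ground truth
#'
#' @slot origin numeric (lat, lon) of the deme actually used as source.
#' @slot demes data.frame per deme: \code{lat}, \code{lon}, \code{step}
#'   (colonisation step, 0 at the origin), \code{expected_h} (closed-form
#'   drift expectation at mutationRate 0), \code{realized_h} (mean unbiased
#'   heterozygosity of the simulated deme).
#' @export
setClass("SyntheticTruth",
  representation(origin = "numeric", demes = "data.frame"))
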