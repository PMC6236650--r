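# Fixture builders and independent oracles shared across the suite.

# Small deterministic table: n samples on a lat/lon ramp, L loci with a
# fixed allele alphabet, optional missing calls.
makeTable <- function(n = 10, L = 4, seed = 1, missing = 0,
                      latRange = c(30, 40), lonRange = c(95, 115)) {
  set.seed(seed)
  g <- matrix(as.character(sample(10:14, n * L, replace = TRUE)),
              nrow = n, dimnames = list(NULL, sprintf("locus_%02d", 1:L)))
  if (missing > 0) g[runif(n * L) < missing] <- NA_character_
  SampleTable(
    data.frame(sample_id = sprintf("s%03d", 1:n),
               region = rep_len(c("north", "south"), n),
               latitude = seq(latRange[1], latRange[2], length.out = n),
               longitude = seq(lonRange[1], lonRange[2], length.out = n),
               stringsAsFactors = FALSE),
    g)
}

# Pair-enumeration oracle for Nei's unbiased gene diversity: the fraction
# of unordered pairs of copies that differ.
pairEnumH <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  same <- sum(counts * (counts - 1) / 2)
  1 - same / (n * (n - 1) / 2)
}

# Direct textbook product-moment correlation.
directPearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Spherical-law-of-cosines great-circle distance (independent of the
# haversine form used by the package).
slocKm <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  6371.0088 * acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))))
}

# Brute-force kernel acceptance: O(nodes x samples) scan with no chunking,
# no deduplication.
bruteKernels <- function(table, grid, radiusKm = 500, minSamples = 5) {
  geo <- geolocatedSubset(table)
  co <- coordinates(geo)
  nodes <- gridNodes(grid)
  out <- list()
  for (k in seq_len(nrow(nodes))) {
    d <- mapply(function(la, lo) haversineKm(nodes$lat[k], nodes$lon[k],
                                             la, lo),
                co$latitude, co$longitude)
    m <- which(d <= radiusKm)
    if (length(m) >= minSamples)
      out[[length(out) + 1L]] <- list(lat = nodes$lat[k],
                                      lon = nodes$lon[k],
                                      members = sort(sampleIDs(geo)[m]))
  }
  out
}

# Brute-force per-kernel mean unbiased heterozygosity, recomputed locus by
# locus from raw calls.
bruteKernelH <- function(memberIDs, table) {
  g <- genotypes(table)[match(memberIDs, sampleIDs(table)), , drop = FALSE]
  hs <- apply(g, 2, function(col) {
    calls <- unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE))
    if (length(calls) < 2) return(NA_real_)
    pairEnumH(table(calls))
  })
  mean(hs, na.rm = TRUE)
}

# All allele-count vectors with total n and at most k alleles (ordered
# compositions; relabelling invariance is tested separately).
allCountVectors <- function(n, k) {
  if (k == 1) return(list(n))
  out <- list()
  for (first in 0:n)
    for (rest in allCountVectors(n - first, k - 1))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}
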