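#' Build a serial-founder simulator configuration
#'
#' Defaults describe a realistic desk-scale landrace panel: a 20 x 10
#' degree continental domain colonised from an interior origin on a 1-degree
#' deme lattice, an 8-copy founding bottleneck per colonisation step (strong
#' enough for a clear serial-founder diversity cline), demes of 120 allele
#' copies, 16 microsatellite loci mutating stepwise at 5e-4 per copy per
#' generation, and 200 sampled accessions with 2% missing calls.
#'
#' @param origin numeric (lat, lon) of the expansion source.
#' @param latRange,lonRange domain bounds in decimal degrees.
#' @param demeStep lattice spacing (degrees).
#' @param founderCopies bottleneck size per colonisation step.
#' @param demeCapacity allele copies per deme at capacity.
#' @param generationsPerStep Wright-Fisher generations between steps.
#' @param mutationRate per-copy per-generation stepwise mutation rate.
#' @param nLoci number of loci.
#' @param alleleRange admissible repeat-length range (reflecting bounds).
#' @param nSamples accessions to sample.
#' @param sampling "uniform" over demes, or "clustered" (samples
#'   concentrated in a random subset of demes, emulating uneven germplasm
#'   collection).
#' @param missingRate per-call missing probability.
#' @param jitterDeg within-deme coordinate jitter; 0 places samples at deme
#'   centres.
#' @param seed RNG seed.
#' @return a validated [ExpansionConfig-class].
#' @export
expansionConfig <- function(origin = c(35, 105), latRange = c(30, 40),
                            lonRange = c(95, 115), demeStep = 1,
                            founderCopies = 8, demeCapacity = 120,
                            generationsPerStep = 3, mutationRate = 5e-4,
                            nLoci = 16, alleleRange = c(10, 30),
                            nSamples = 200, sampling = "uniform",
                            missingRate = 0.02, jitterDeg = 0, seed = 1) {
  new("ExpansionConfig", origin = as.numeric(origin),
      latRange = as.numeric(latRange), lonRange = as.numeric(lonRange),
      demeStep = as.numeric(demeStep),
      founderCopies = as.integer(founderCopies),
      demeCapacity = as.integer(demeCapacity),
      generationsPerStep = as.integer(generationsPerStep),
      mutationRate = as.numeric(mutationRate), nLoci = as.integer(nLoci),
      alleleRange = as.integer(alleleRange),
      nSamples = as.integer(nSamples), sampling = sampling,
      missingRate = as.numeric(missingRate),
      jitterDeg = as.numeric(jitterDeg), seed = as.integer(seed))
}

setMethod("show", "ExpansionConfig", function(object) {
  cat(sprintf(
    "ExpansionConfig: origin (%g N, %g E), domain %g..%g N x %g..%g E\n",
    object@origin[1], object@origin[2], object@latRange[1],
    object@latRange[2], object@lonRange[1], object@lonRange[2]))
  cat(sprintf(
    "  %d loci, bottleneck %d of %d copies, %d gen/step, mu = %g\n",
    object@nLoci, object@founderCopies, object@demeCapacity,
    object@generationsPerStep, object@mutationRate))
  cat(sprintf("  %d samples (%s), missing %g, seed %d\n",
              object@nSamples, object@sampling, object@missingRate,
              object@seed))
})

## one Wright-Fisher generation with stepwise mutation, reflecting bounds
.wfGeneration <- function(pool, size, mu, lo, hi) {
  pool <- pool[sample.int(nrow(pool), size, replace = TRUE), ,
               drop = FALSE]
  if (mu > 0) {
    hit <- which(stats::runif(length(pool)) < mu)
    if (length(hit)) {
      step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
      v <- pool[hit] + step
      v[v < lo] <- lo + 1L
      v[v > hi] <- hi - 1L
      pool[hit] <- v
    }
  }
  pool
}

.demeMeanH <- function(mat) {
  mean(apply(mat, 2, function(a) unbiasedH(table(a))), na.rm = TRUE)
}

#' Simulate a serial-founder range expansion
#'
#' Colonises a deme lattice breadth-first (rook adjacency) from the deme
#' nearest the configured origin. The origin deme is filled with allele
#' copies drawn uniformly from the ancestral repeat-length range; every
#' subsequent deme is founded by \code{founderCopies} copies drawn
#' (Wright-Fisher style, with replacement) from the pooled copies of its
#' already-colonised neighbouring demes, then grown to
#' \code{demeCapacity} through \code{generationsPerStep} Wright-Fisher
#' generations with stepwise mutation. Because each founding event is a
#' bottleneck, expected heterozygosity decays along every colonisation path
#' — the monotonic diversity cline the origin scan assumes. Individuals are
#' haploid allele vectors (one copy per locus), matching the single-call
#' scoring convention for strongly selfing crops.
#'
#' @param config an [ExpansionConfig-class].
#' @return list with elements \code{table} (a [SampleTable-class] of
#'   \code{nSamples} accessions placed at their deme coordinates) and
#'   \code{truth} (a [SyntheticTruth-class] with the origin and per-deme
#'   expected/realised heterozygosity trajectory). Deterministic given
#'   \code{config@seed}.
#' @export
simulateExpansion <- function(config) {
  stopifnot(is(config, "ExpansionConfig"))
  validObject(config)
  set.seed(config@seed)
  lats <- .axisSeq(config@latRange[1], config@latRange[2], config@demeStep)
  lons <- .axisSeq(config@lonRange[1], config@lonRange[2], config@demeStep)
  nr <- length(lats); nc <- length(lons)
  demeLat <- rep(lats, times = nc)
  demeLon <- rep(lons, each = nr)
  nDemes <- nr * nc
  idx <- function(i, j) (j - 1L) * nr + i
  o <- c(which.min(abs(lats - config@origin[1])),
         which.min(abs(lons - config@origin[2])))
  originDeme <- idx(o[1], o[2])

  ## breadth-first colonisation order over the rook-adjacency lattice
  step <- rep(NA_integer_, nDemes)
  parent <- rep(NA_integer_, nDemes)
  step[originDeme] <- 0L
  queue <- originDeme
  order <- integer(0)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    order <- c(order, cur)
    i <- ((cur - 1L) %% nr) + 1L
    j <- ((cur - 1L) %/% nr) + 1L
    nb <- c(if (i > 1L) idx(i - 1L, j), if (i < nr) idx(i + 1L, j),
            if (j > 1L) idx(i, j - 1L), if (j < nc) idx(i, j + 1L))
    nb <- nb[is.na(step[nb])]
    step[nb] <- step[cur] + 1L
    parent[nb] <- cur
    queue <- c(queue, nb)
  }

  lo <- config@alleleRange[1]; hi <- config@alleleRange[2]
  L <- config@nLoci
  cap <- config@demeCapacity
  demes <- vector("list", nDemes)
  demes[[originDeme]] <- matrix(
    sample(lo:hi, cap * L, replace = TRUE), nrow = cap, ncol = L)
  nbrsOf <- function(d) {
    i <- ((d - 1L) %% nr) + 1L
    j <- ((d - 1L) %/% nr) + 1L
    c(if (i > 1L) idx(i - 1L, j), if (i < nr) idx(i + 1L, j),
      if (j > 1L) idx(i, j - 1L), if (j < nc) idx(i, j + 1L))
  }
  for (d in order[-1]) {
    ## wavefront mixing: the founding pool is every already-colonised
    ## adjacent deme (the parent is always among them), so neighbouring
    ## demes at the same front share recent ancestry, as on a real
    ## expansion wave
    src <- nbrsOf(d)
    src <- src[!vapply(demes[src], is.null, logical(1))]
    srcPool <- do.call(rbind, demes[src])
    ## Wright-Fisher bottleneck: founders drawn with replacement, so
    ## expected gene diversity decays by (1 - 1/founderCopies) per step
    founders <- srcPool[
      sample.int(nrow(srcPool), config@founderCopies, replace = TRUE), ,
      drop = FALSE]
    pool <- founders
    for (g in seq_len(config@generationsPerStep))
      pool <- .wfGeneration(pool, cap, config@mutationRate, lo, hi)
    demes[[d]] <- pool
  }

  realized <- vapply(demes, .demeMeanH, numeric(1))
  h0 <- realized[originDeme]
  lossPerStep <- (1 - 1 / config@founderCopies) *
    (1 - 1 / cap)^config@generationsPerStep
  expected <- h0 * lossPerStep^step

  ## sample accessions
  demePick <- switch(config@sampling,
    uniform = sample.int(nDemes, config@nSamples, replace = TRUE),
    clustered = {
      hubs <- sample.int(nDemes, max(3L, nDemes %/% 10L))
      sample(hubs, config@nSamples, replace = TRUE)
    })
  geno <- matrix(NA_character_, config@nSamples, L,
                 dimnames = list(NULL, sprintf("locus_%02d", seq_len(L))))
  for (s in seq_len(config@nSamples)) {
    ind <- demes[[demePick[s]]][sample.int(cap, 1L), ]
    geno[s, ] <- as.character(ind)
  }
  if (config@missingRate > 0)
    geno[stats::runif(length(geno)) < config@missingRate] <- NA_character_
  lat <- demeLat[demePick]
  lon <- demeLon[demePick]
  if (config@jitterDeg > 0) {
    lat <- lat + stats::runif(config@nSamples, -1, 1) * config@jitterDeg
    lon <- lon + stats::runif(config@nSamples, -1, 1) * config@jitterDeg
  }
  samples <- data.frame(
    sample_id = sprintf("sim%04d", seq_len(config@nSamples)),
    region = sprintf("deme_%03d", demePick),
    latitude = lat, longitude = lon, stringsAsFactors = FALSE)
  table <- SampleTable(samples, geno)
  truth <- new("SyntheticTruth",
               origin = c(lats[o[1]], lons[o[2]]),
               demes = data.frame(lat = demeLat, lon = demeLon,
                                  step = step, expected_h = expected,
                                  realized_h = realized))
  list(table = table, truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: origin (%g N, %g E), %d demes, max step %d\n",
    object@origin[1], object@origin[2], nrow(object@demes),
    max(object@demes$step)))
})

#' Destroy geographic structure by reassigning genotypes to locations
#'
#' Randomly permutes whole genotype vectors (all loci jointly, plus the
#' GBSSI genotypes) across the sampling coordinates, leaving every
#' coordinate and the multiset of genotype vectors unchanged. The result is
#' a structureless negative control for the origin scan.
#'
#' @param table a [SampleTable-class].
#' @param seed integer RNG seed.
#' @return a [SampleTable-class] with shuffled genotype-to-location
#'   assignment.
#' @export
nullShuffle <- function(table, seed = 1) {
  stopifnot(is(table, "SampleTable"))
  n <- nSamples(table)
  if (n < 2) return(table)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  s <- sampleData(table)
  s$gbssi_s <- s$gbssi_s[perm]
  s$gbssi_l <- s$gbssi_l[perm]
  SampleTable(s, genotypes(table)[perm, , drop = FALSE],
              copies = copiesPerSample(table))
}

#' Write the simulation ground truth as a delimited sidecar
#'
#' @param truth a [SyntheticTruth-class].
#' @param path destination file (TSV; the origin is a comment line).
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  writeLines(sprintf("# origin_lat=%g origin_lon=%g",
                     truth@origin[1], truth@origin[2]), path)
  suppressWarnings(utils::write.table(truth@demes, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
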