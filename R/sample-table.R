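#' Construct a SampleTable
#'
#' @param samples data.frame with columns \code{sample_id}, \code{region},
#'   \code{latitude}, \code{longitude}, \code{gbssi_s}, \code{gbssi_l}
#'   (missing metadata columns are added as \code{NA}); extra columns are
#'   kept as opaque metadata.
#' @param genotypes character matrix (samples x loci) of allele calls,
#'   \code{NA} for missing; column names are the locus names. Multiple
#'   scored copies per sample are joined by \code{"/"}.
#' @param copies allele copies scored per sample per locus (default 1,
#'   the convention for strongly selfing crops such as broomcorn millet).
#' @return a validated [SampleTable-class].
#' @examples
#' g <- matrix(c("10", "12", "10", "14"), nrow = 2,
#'             dimnames = list(NULL, c("L1", "L2")))
#' tab <- SampleTable(data.frame(sample_id = c("a", "b"),
#'                               latitude = c(35, 36),
#'                               longitude = c(100, 101)), g)
#' nSamples(tab)
#' @export
SampleTable <- function(samples, genotypes, copies = 1L) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("region", "gbssi_s", "gbssi_l"))
    if (is.null(samples[[col]]))
      samples[[col]] <- rep(NA_character_, nrow(samples))
  samples$sample_id <- as.character(samples$sample_id)
  samples$latitude <- as.numeric(samples$latitude)
  samples$longitude <- as.numeric(samples$longitude)
  genotypes <- as.matrix(genotypes)
  if (length(genotypes)) storage.mode(genotypes) <- "character"
  genotypes[!is.na(genotypes) & genotypes == ""] <- NA_character_
  rownames(genotypes) <- samples$sample_id
  new("SampleTable", samples = samples, genotypes = genotypes,
      copies = as.integer(copies))
}

#' @rdname accessors
#' @export
setMethod("nSamples", "SampleTable", function(x) nrow(x@samples))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SampleTable", function(x) x@samples$sample_id)

#' @rdname accessors
#' @export
setMethod("sampleData", "SampleTable", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("coordinates", "SampleTable", function(x)
  data.frame(latitude = x@samples$latitude,
             longitude = x@samples$longitude))

#' @rdname accessors
#' @export
setMethod("genotypes", "SampleTable", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("locusNames", "SampleTable", function(x) colnames(x@genotypes))

#' @rdname accessors
#' @export
setMethod("copiesPerSample", "SampleTable", function(x) x@copies)

setMethod("show", "SampleTable", function(object) {
  n <- nSamples(object)
  L <- ncol(object@genotypes)
  geo <- sum(stats::complete.cases(coordinates(object)))
  miss <- if (length(object@genotypes))
    mean(is.na(object@genotypes)) else 0
  cat(sprintf("SampleTable: %d samples, %d loci (%d copies/sample)\n",
              n, L, object@copies))
  cat(sprintf("  geolocated: %d/%d; missing genotype calls: %.1f%%\n",
              geo, n, 100 * miss))
  extra <- setdiff(names(object@samples),
                   c("sample_id", "region", "latitude", "longitude",
                     "gbssi_s", "gbssi_l"))
  if (length(extra))
    cat("  extra metadata:", paste(extra, collapse = ", "), "\n")
})

#' Restrict a table to usably geolocated samples
#'
#' Drops every record lacking either coordinate (analyses of landrace
#' collections routinely exclude accessions with only vague provenance).
#' Row order is preserved and the operation is idempotent.
#'
#' @param table a [SampleTable-class].
#' @return a [SampleTable-class] containing the geolocated records only.
#' @export
geolocatedSubset <- function(table) {
  stopifnot(is(table, "SampleTable"))
  keep <- !is.na(table@samples$latitude) & !is.na(table@samples$longitude)
  SampleTable(table@samples[keep, , drop = FALSE],
              table@genotypes[keep, , drop = FALSE],
              copies = table@copies)
}

## ---- internal genotype machinery -------------------------------------

## Split multi-copy cells into per-copy allele calls.
## Returns list of character matrices, one per copy slot (n x L).
.alleleCalls <- function(table) {
  g <- genotypes(table)
  P <- copiesPerSample(table)
  if (P == 1L) return(list(g))
  out <- vector("list", P)
  parts <- strsplit(ifelse(is.na(g), "", g), "/", fixed = TRUE)
  for (p in seq_len(P)) {
    m <- matrix(vapply(parts, function(z)
      if (length(z) >= p && nzchar(z[p]) && z[p] != "NA") z[p]
      else NA_character_, character(1)),
      nrow = nrow(g), dimnames = dimnames(g))
    out[[p]] <- m
  }
  out
}

## Sparse allele-indicator encoding shared by kernel diversity, the
## permutation engine and the PCA design matrix.
##   X     : n x A sparse matrix of per-sample allele-copy counts
##   Lmap  : L x A sparse locus aggregator (1 where column belongs to locus)
##   alleles: data.frame(locus, allele) describing the A columns
.alleleIndicator <- function(table) {
  calls <- .alleleCalls(table)
  n <- nSamples(table)
  L <- length(locusNames(table))
  levs <- vector("list", L)
  for (l in seq_len(L)) {
    v <- unlist(lapply(calls, function(m) m[, l]), use.names = FALSE)
    levs[[l]] <- sort(unique(v[!is.na(v)]))
  }
  nlev <- lengths(levs)
  offs <- c(0L, cumsum(nlev))
  A <- offs[L + 1L]
  ii <- jj <- integer(0)
  for (l in seq_len(L)) {
    if (!nlev[l]) next
    for (m in calls) {
      idx <- match(m[, l], levs[[l]])
      ok <- which(!is.na(idx))
      ii <- c(ii, ok)
      jj <- c(jj, offs[l] + idx[ok])
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, A))
  Lmap <- Matrix::sparseMatrix(i = rep.int(seq_len(L), nlev),
                               j = seq_len(A), x = 1, dims = c(L, A))
  alleles <- data.frame(
    locus = rep.int(locusNames(table), nlev),
    allele = unlist(levs, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(X = X, Lmap = Lmap, alleles = alleles)
}
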