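#' Nei's unbiased gene diversity for one locus
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with \eqn{n} the
#' number of scored allele copies and \eqn{p_i} the allele frequencies.
#' Equals the probability that two copies drawn without replacement carry
#' different alleles, hence the sample-size correction. Undefined
#' (\code{NA}) when fewer than two copies are scored.
#'
#' @param counts named non-negative integer vector of allele-copy counts
#'   (missing calls simply do not appear in the counts).
#' @return diversity in [0, 1], or \code{NA} when n < 2.
#' @examples
#' unbiasedH(c(A = 4))          # monomorphic: 0
#' unbiasedH(c(A = 1, B = 1))   # two distinct copies: 1
#' unbiasedH(c(A = 3, B = 1))   # 3 unequal pairs of 6: 0.5
#' @export
unbiasedH <- function(counts) {
  if (any(counts < 0)) stop("allele counts must be non-negative")
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Pearson product-moment correlation
#'
#' As \code{stats::cor}, but returning \code{NA} (rather than an error or
#' \code{NaN}) when either vector is constant, since a zero-variance
#' diversity vector carries no origin signal and must be flagged, not
#' forced to 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or \code{NA} when undefined.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  if (stats::var(x) <= .Machine$double.eps ||
      stats::var(y) <= .Machine$double.eps) return(NA_real_)
  stats::cor(x, y)
}

## Weighted Pearson correlation (weights = kernel multiplicities), NA when
## either weighted variance vanishes.
.wPearson <- function(x, y, w) {
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 2) return(NA_real_)
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2); syy <- sum(w * (y - my)^2)
  if (sxx <= 1e-300 || syy <= 1e-300) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(sxx * syy)
}

## Row-wise weighted Pearson of each row of D against y.
.wPearsonRows <- function(D, y, w) {
  ok <- is.finite(y) & is.finite(w)
  D <- D[, ok, drop = FALSE]; y <- y[ok]; w <- w[ok]
  if (length(y) < 2) return(rep(NA_real_, nrow(D)))
  sw <- sum(w)
  my <- sum(w * y) / sw
  yc <- y - my
  syy <- sum(w * yc^2)
  mx <- as.vector(D %*% w) / sw
  Dc <- D - mx
  sxy <- as.vector(Dc %*% (w * yc))
  sxx <- as.vector((Dc * Dc) %*% w)
  r <- sxy / sqrt(sxx * syy)
  r[sxx <= 1e-300 | syy <= 1e-300] <- NA_real_
  r
}

## Per-kernel, per-locus unbiased heterozygosity from an allele-count
## matrix C (alleles x kernels), aggregated by the locus map.
## Returns list(h = L x K matrix with NA where n < 2, hMean = length-K).
.hFromCounts <- function(C, Lmap) {
  C <- as.matrix(C)
  N <- as.matrix(Lmap %*% C)            # copies per locus per kernel
  S <- as.matrix(Lmap %*% (C * C))      # sum of squared counts
  h <- (N / (N - 1)) * (1 - S / (N * N))
  h[N < 2] <- NA_real_
  hMean <- colMeans(h, na.rm = TRUE)
  hMean[is.nan(hMean)] <- NA_real_
  list(h = h, hMean = hMean)
}

#' Mean unbiased heterozygosity of each accepted kernel
#'
#' For every kernel, computes Nei's unbiased gene diversity per locus over
#' the member samples' allele calls (missing calls are excluded per locus;
#' loci with fewer than two scored copies are flagged undefined) and
#' averages across the defined loci.
#'
#' @param kernels a [KernelSet-class].
#' @param table the [SampleTable-class] the kernels were accepted from.
#' @return data.frame with one row per kernel node (\code{lat}, \code{lon},
#'   \code{n_members}, \code{h_mean}); the per-locus matrix
#'   (loci x kernel nodes) is attached as attribute \code{"h_by_locus"}.
#'   Diversity is computed once per distinct member set and expanded to the
#'   nodes. Kernels whose every locus is undefined get \code{h_mean = NA}.
#' @export
kernelDiversity <- function(kernels, table) {
  stopifnot(is(kernels, "KernelSet"), is(table, "SampleTable"))
  kt <- kernelCenters(kernels)
  if (!nrow(kt)) {
    out <- data.frame(lat = numeric(0), lon = numeric(0),
                      n_members = integer(0), h_mean = numeric(0))
    attr(out, "h_by_locus") <-
      matrix(NA_real_, length(locusNames(table)), 0)
    return(out)
  }
  mem <- kernels@members  # distinct member sets
  bad <- !unlist(mem) %in% sampleIDs(table)
  if (any(bad)) stop("kernel member id(s) absent from the table")
  enc <- .alleleIndicator(table)
  Mem <- .membershipMatrix(mem, sampleIDs(table))
  C <- Matrix::crossprod(enc$X, Mem)
  hh <- .hFromCounts(C, enc$Lmap)
  out <- kt[c("lat", "lon", "n_members")]
  out$h_mean <- hh$hMean[kt$set]
  h <- hh$h[, kt$set, drop = FALSE]
  rownames(h) <- locusNames(table)
  attr(out, "h_by_locus") <- h
  out
}

## n x K sparse 0/1 membership matrix from member-id lists.
.membershipMatrix <- function(members, ids) {
  i <- match(unlist(members, use.names = FALSE), ids)
  j <- rep.int(seq_along(members), lengths(members))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(ids), length(members)))
}

#' Serialise kernel diversities to delimited text
#'
#' @param kdiv output of [kernelDiversity()].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeKernelDiversity <- function(kdiv, path) {
  utils::write.table(kdiv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
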