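#' Allele-indicator genotype matrix
#'
#' Encodes the table as samples x (locus, allele) indicator columns whose
#' value is the fraction of that sample's scored copies carrying the allele
#' (0/1 under single-copy scoring), the standard design matrix for genotype
#' PCA. A sample missing a locus entirely receives the column means of that
#' locus's columns (mean imputation keeps the sample without biasing the
#' column centroids); zero-variance columns are dropped with a warning
#' listing how many.
#'
#' @param table a [SampleTable-class] with >= 2 samples.
#' @param dropZeroVar drop constant columns (default TRUE).
#' @return numeric matrix with attribute \code{"alleles"} (data.frame of
#'   locus/allele per column). Row sums over a locus's columns equal 1 for
#'   samples scored at that locus.
#' @export
genotypeMatrix <- function(table, dropZeroVar = TRUE) {
  stopifnot(is(table, "SampleTable"))
  if (nSamples(table) < 2) stop("need at least two samples")
  enc <- .alleleIndicator(table)
  M <- as.matrix(enc$X)
  scored <- as.matrix(enc$X %*% Matrix::t(enc$Lmap))  # copies per locus
  lmap <- as.matrix(enc$Lmap)
  for (l in seq_len(nrow(lmap))) {
    cols <- which(lmap[l, ] > 0)
    if (!length(cols)) next
    nsc <- scored[, l]
    M[nsc > 0, cols] <- M[nsc > 0, cols, drop = FALSE] / nsc[nsc > 0]
    if (any(nsc == 0)) {
      mu <- colMeans(M[nsc > 0, cols, drop = FALSE])
      M[nsc == 0, cols] <- rep(mu, each = sum(nsc == 0))
    }
  }
  colnames(M) <- paste(enc$alleles$locus, enc$alleles$allele, sep = ".")
  rownames(M) <- sampleIDs(table)
  keep <- rep(TRUE, ncol(M))
  if (dropZeroVar) {
    keep <- apply(M, 2, stats::var) > .Machine$double.eps
    if (!any(keep))
      warning("all columns are constant (monomorphic table)")
    else if (!all(keep))
      warning(sum(!keep), " zero-variance column(s) dropped")
  }
  out <- M[, keep, drop = FALSE]
  attr(out, "alleles") <- enc$alleles[keep, , drop = FALSE]
  out
}

#' Principal components analysis of a genotype matrix
#'
#' Eigendecomposition of the covariance of the column-centred (by default
#' unscaled) allele-indicator matrix. The per-component variance fraction is
#' the eigenvalue over the trace, the quantity conventionally reported as
#' "PC1 accounted for x% of the variance".
#'
#' @param x a [SampleTable-class] or a matrix from [genotypeMatrix()].
#' @param nComponents components to return (truncated to the matrix rank,
#'   with a warning, when it exceeds it).
#' @param scale. also scale columns to unit variance (default FALSE).
#' @return list with \code{scores} (samples x components),
#'   \code{varianceFraction} (per returned component) and \code{sdev}
#'   (all singular values / sqrt(n - 1)).
#' @export
pcaGenotypes <- function(x, nComponents = 2, scale. = FALSE) {
  M <- if (is(x, "SampleTable")) genotypeMatrix(x) else as.matrix(x)
  if (nrow(M) < 2) stop("need at least two rows")
  fit <- stats::prcomp(M, center = TRUE, scale. = scale.)
  ev <- fit$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (nComponents > rank) {
    warning("nComponents exceeds matrix rank (", rank, "); truncated")
    nComponents <- rank
  }
  list(scores = fit$x[, seq_len(nComponents), drop = FALSE],
       varianceFraction = ev[seq_len(nComponents)] / sum(ev),
       sdev = fit$sdev)
}

#' Read Bayesian-clustering replicate log-likelihoods
#'
#' Parses the simple delimited schema used to summarise external clustering
#' runs (Instruct/STRUCTURE-style): one row per replicate run with columns
#' \code{K}, \code{run}, \code{lnP} (the run's log-probability of the
#' data). The clustering itself is always run externally; only its log
#' summary enters this package.
#'
#' @param path delimited file with header K, run, lnP.
#' @param sep field separator (default tab).
#' @return data.frame(K, run, lnP).
#' @export
readClusterRuns <- function(path, sep = "\t") {
  runs <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("K", "run", "lnP")
  if (!all(need %in% names(runs)))
    stop("cluster run table needs columns: ", paste(need, collapse = ", "))
  runs[need]
}

#' Evanno delta-K from clustering replicate log-likelihoods
#'
#' For each interior K of a contiguous range,
#' \eqn{\Delta K = \mathrm{mean}_{runs} |L(K+1) - 2L(K) + L(K-1)| /
#' \mathrm{sd}_{runs}(L(K))}: the mean absolute second difference of the
#' log-probability of the data, scaled by the replicate standard deviation.
#' A sharp elbow in L(K) yields a peak at the best-supported K. Boundary K
#' values are undefined by construction; K values with zero replicate
#' standard deviation are flagged undefined rather than infinite.
#'
#' @param runs data.frame(K, run, lnP) as from [readClusterRuns()], with
#'   >= 3 consecutive K values and >= 2 replicates per K.
#' @return data.frame(K, meanLnP, sdLnP, deltaK) over all K, with
#'   \code{deltaK = NA} at the boundaries and wherever undefined.
#' @export
deltaK <- function(runs) {
  ks <- sort(unique(runs$K))
  if (length(ks) < 3 || any(diff(ks) != 1))
    stop("need at least 3 consecutive K values")
  reps <- table(runs$K)
  if (any(reps < 2)) stop("need >= 2 replicates per K")
  L <- tapply(runs$lnP, list(runs$run, runs$K), mean)
  L <- L[, as.character(ks), drop = FALSE]
  meanL <- colMeans(L, na.rm = TRUE)
  sdL <- apply(L, 2, stats::sd, na.rm = TRUE)
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    d2 <- abs(L[, i + 1] - 2 * L[, i] + L[, i - 1])
    if (is.na(sdL[i]) || sdL[i] <= 0) next
    dk[i] <- mean(d2, na.rm = TRUE) / sdL[i]
  }
  data.frame(K = ks, meanLnP = unname(meanL), sdLnP = unname(sdL),
             deltaK = dk)
}

#' Generate synthetic clustering logs with a known elbow
#'
#' Builds replicate log-likelihood tables whose mean L(K) rises steeply up
#' to \code{elbowAt} and flattens beyond it, so the Evanno statistic should
#' peak at \code{elbowAt}. Used to exercise [deltaK()] without running any
#' external clustering software.
#'
#' @param kRange integer vector of consecutive K values (default 1:12).
#' @param nRuns replicates per K (default 10, the usual protocol).
#' @param elbowAt true number of clusters.
#' @param slopes numeric(2): lnP gain per K before and after the elbow.
#' @param noiseSD replicate standard deviation of lnP.
#' @param seed RNG seed.
#' @return data.frame(K, run, lnP).
#' @export
simulateClusterLogs <- function(kRange = 1:12, nRuns = 10, elbowAt = 3,
                                slopes = c(400, 10), noiseSD = 20,
                                seed = 1) {
  set.seed(as.integer(seed))
  meanL <- -10000 + cumsum(ifelse(kRange <= elbowAt, slopes[1], slopes[2]))
  out <- expand.grid(run = seq_len(nRuns), K = kRange)
  out$lnP <- meanL[match(out$K, kRange)] +
    stats::rnorm(nrow(out), sd = noiseSD)
  out[c("K", "run", "lnP")]
}
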