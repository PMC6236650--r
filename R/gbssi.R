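#' Summarise GBSSI waxy-gene genotypes
#'
#' Tabulates allele frequencies at the two duplicated granule-bound starch
#' synthase I loci — GBSSI-S (alleles S0 wild type, S-15 waxy) and GBSSI-L
#' (LC wild type; LY and Lf waxy) — overall or per group, and classifies
#' each sample's endosperm phenotype. The S0 allele is dominant, so any
#' sample carrying S0 is phenotypically wild type (non-waxy). Samples
#' homozygous S-15/S-15 are waxy at the S locus; when \code{useL = TRUE}
#' (the default) those whose GBSSI-L genotype carries no wild-type LC
#' allele are promoted to fully waxy, since the L-locus waxy alleles
#' combine with S-15 to abolish amylose altogether. The L-locus refinement
#' is an interpretive rule and can be switched off.
#'
#' @param table a [SampleTable-class] with GBSSI genotypes for >= 1 sample.
#' @param grouping \code{NULL} (one overall group), the name of a
#'   \code{sampleData} column, or a vector of group labels per sample.
#' @param useL apply the L-locus fully-waxy refinement (default TRUE).
#' @return list with \code{alleleFreqS} and \code{alleleFreqL}
#'   (data.frames: group, allele, count, freq; missing genotypes excluded
#'   from denominators) and \code{phenotypes} (data.frame: sample_id,
#'   group, phenotype in \{"wild_type", "waxy", "fully_waxy", NA\}).
#' @export
gbssiSummary <- function(table, grouping = NULL, useL = TRUE) {
  stopifnot(is(table, "SampleTable"))
  s <- sampleData(table)
  if (all(is.na(s$gbssi_s)) && all(is.na(s$gbssi_l)))
    stop("no GBSSI genotypes present")
  grp <- if (is.null(grouping)) rep("all", nrow(s))
    else if (length(grouping) == 1 && grouping %in% names(s))
      as.character(s[[grouping]])
    else as.character(grouping)
  if (length(grp) != nrow(s))
    stop("grouping length does not match sample count")

  tallyLocus <- function(geno) {
    alleles <- strsplit(geno, "/", fixed = TRUE)
    g <- rep(grp, lengths(alleles))
    a <- unlist(alleles, use.names = FALSE)
    keep <- !is.na(a)
    if (!any(keep))
      return(data.frame(group = character(0), allele = character(0),
                        count = integer(0), freq = numeric(0)))
    tab <- as.data.frame(table(group = g[keep], allele = a[keep]),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "count"
    tot <- tapply(tab$count, tab$group, sum)
    tab$freq <- tab$count / as.vector(tot[tab$group])
    tab[tab$count >= 0, ]
  }

  hasS0 <- !is.na(s$gbssi_s) & grepl("S0", s$gbssi_s, fixed = TRUE)
  homS15 <- !is.na(s$gbssi_s) & s$gbssi_s == "S-15/S-15"
  noLC <- !is.na(s$gbssi_l) & !grepl("LC", s$gbssi_l, fixed = TRUE)
  phen <- rep(NA_character_, nrow(s))
  phen[hasS0] <- "wild_type"
  phen[homS15] <- "waxy"
  if (useL) phen[homS15 & noLC] <- "fully_waxy"

  list(alleleFreqS = tallyLocus(s$gbssi_s),
       alleleFreqL = tallyLocus(s$gbssi_l),
       phenotypes = data.frame(sample_id = s$sample_id, group = grp,
                               phenotype = phen,
                               stringsAsFactors = FALSE))
}
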