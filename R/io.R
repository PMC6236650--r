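#' Describe the on-disk dialect of a sample table
#'
#' The delimited layout is: one header row, then one row per accession with
#' columns \code{sample_id}, \code{region}, \code{latitude},
#' \code{longitude}, one column per locus, \code{gbssi_s}, \code{gbssi_l};
#' unknown extra columns are carried through untouched.
#'
#' @param sep field delimiter (default comma).
#' @param missingCodes strings accepted as missing on input; the first
#'   element is the canonical token written on output.
#' @param copies allele copies scored per sample per locus (P).
#' @param locusPrefix locus columns are recognised by this name prefix when
#'   \code{locusCols} is not given.
#' @param locusCols explicit character vector of locus column names, or
#'   \code{NULL} to use the prefix rule.
#' @param idCol,regionCol,latCol,lonCol,gbssiSCol,gbssiLCol column names.
#' @return a dialect list understood by [readSamples()]/[writeSamples()].
#' @export
sampleDialect <- function(sep = ",", missingCodes = c("NA", ""),
                          copies = 1L, locusPrefix = "locus_",
                          locusCols = NULL, idCol = "sample_id",
                          regionCol = "region", latCol = "latitude",
                          lonCol = "longitude", gbssiSCol = "gbssi_s",
                          gbssiLCol = "gbssi_l") {
  list(sep = sep, missingCodes = missingCodes, copies = as.integer(copies),
       locusPrefix = locusPrefix, locusCols = locusCols, idCol = idCol,
       regionCol = regionCol, latCol = latCol, lonCol = lonCol,
       gbssiSCol = gbssiSCol, gbssiLCol = gbssiLCol)
}

#' Read a delimited sample table
#'
#' Rows whose coordinate cells cannot be parsed as numbers are retained with
#' the coordinate flagged missing; coordinates that parse but fall outside
#' the valid range raise an error naming the offending row, as do duplicate
#' sample ids.
#'
#' @param path file to read.
#' @param dialect a [sampleDialect()] list.
#' @return a validated [SampleTable-class].
#' @export
readSamples <- function(path, dialect = sampleDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  for (col in c(dialect$idCol, dialect$latCol, dialect$lonCol))
    if (!col %in% names(raw))
      stop("malformed header: missing column '", col, "'")
  canon <- function(v) {
    v[v %in% dialect$missingCodes] <- NA_character_
    v
  }
  raw[] <- lapply(raw, canon)
  lociCols <- if (!is.null(dialect$locusCols)) dialect$locusCols
    else names(raw)[startsWith(names(raw), dialect$locusPrefix)]
  if (!length(lociCols))
    stop("malformed header: no locus columns found (prefix '",
         dialect$locusPrefix, "')")
  numOrNA <- function(v) suppressWarnings(as.numeric(v))
  lat <- numOrNA(raw[[dialect$latCol]])
  lon <- numOrNA(raw[[dialect$lonCol]])
  badLat <- which(!is.na(lat) & (lat < -90 | lat > 90))
  if (length(badLat))
    stop("latitude out of range in row(s) ",
         paste(head(badLat, 5), collapse = ", "))
  badLon <- which(!is.na(lon) & (lon < -180 | lon > 180))
  if (length(badLon))
    stop("longitude out of range in row(s) ",
         paste(head(badLon, 5), collapse = ", "))
  ids <- raw[[dialect$idCol]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  known <- c(dialect$idCol, dialect$regionCol, dialect$latCol,
             dialect$lonCol, dialect$gbssiSCol, dialect$gbssiLCol, lociCols)
  extras <- setdiff(names(raw), known)
  getcol <- function(col) if (col %in% names(raw)) raw[[col]]
    else NA_character_
  samples <- data.frame(sample_id = ids, region = getcol(dialect$regionCol),
                        latitude = lat, longitude = lon,
                        gbssi_s = getcol(dialect$gbssiSCol),
                        gbssi_l = getcol(dialect$gbssiLCol),
                        stringsAsFactors = FALSE)
  for (col in extras) samples[[col]] <- raw[[col]]
  SampleTable(samples, as.matrix(raw[lociCols]), copies = dialect$copies)
}

#' Write a delimited sample table
#'
#' The output is lossless for every field, loadable by [readSamples()]
#' with the same dialect, and byte-stable: the column order is fixed
#' (id, region, coordinates, loci, GBSSI, extras) and missing values are
#' written as the dialect's canonical missing token.
#'
#' @param table a [SampleTable-class].
#' @param path destination file.
#' @param dialect a [sampleDialect()] list.
#' @return \code{path}, invisibly.
#' @export
writeSamples <- function(table, path, dialect = sampleDialect()) {
  stopifnot(is(table, "SampleTable"))
  validObject(table)
  s <- sampleData(table)
  g <- genotypes(table)
  extras <- setdiff(names(s), c("sample_id", "region", "latitude",
                                "longitude", "gbssi_s", "gbssi_l"))
  out <- data.frame(s$sample_id, s$region, as.character(s$latitude),
                    as.character(s$longitude), stringsAsFactors = FALSE)
  names(out) <- c(dialect$idCol, dialect$regionCol, dialect$latCol,
                  dialect$lonCol)
  for (l in colnames(g)) out[[l]] <- g[, l]
  out[[dialect$gbssiSCol]] <- s$gbssi_s
  out[[dialect$gbssiLCol]] <- s$gbssi_l
  for (col in extras) out[[col]] <- as.character(s[[col]])
  miss <- dialect$missingCodes[1]
  out[] <- lapply(out, function(v) ifelse(is.na(v), miss, v))
  if (any(vapply(out, function(v) any(grepl(dialect$sep, v, fixed = TRUE)),
                 logical(1))))
    stop("a field contains the delimiter '", dialect$sep, "'")
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
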