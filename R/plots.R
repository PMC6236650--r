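#' @importFrom ggplot2 ggplot aes geom_raster geom_point geom_polygon
#'   geom_histogram geom_vline scale_fill_gradient2 coord_quickmap labs
#'   theme_minimal annotate
#' @importFrom rlang .data
NULL

#' Map an origin-correlation surface
#'
#' Heatmap of the correlation surface in the conventional palette (red =
#' negative r = plausible origin, blue = positive), optionally overlaid
#' with sample locations and starred candidate sites. Samples lacking
#' coordinates are skipped and their count reported.
#'
#' @param surface an [OriginSurface-class] (interpolate first for a smooth
#'   map).
#' @param samples optional [SampleTable-class] whose geolocated points are
#'   drawn.
#' @param sites optional data.frame(lat, lon, label) of candidate origins.
#' @return a ggplot object.
#' @export
plotOriginSurface <- function(surface, samples = NULL, sites = NULL) {
  stopifnot(is(surface, "OriginSurface"))
  nodes <- gridNodes(surface@grid)
  nodes$r <- as.vector(t(surface@r))
  p <- ggplot(nodes, aes(x = .data$lon, y = .data$lat)) +
    geom_raster(aes(fill = .data$r)) +
    scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                         midpoint = 0, na.value = "grey90") +
    coord_quickmap() + theme_minimal() +
    labs(x = "longitude", y = "latitude", fill = "r")
  if (!is.null(samples)) {
    co <- coordinates(samples)
    nSkip <- sum(!stats::complete.cases(co))
    if (nSkip) message(nSkip, " sample(s) without coordinates skipped")
    co <- co[stats::complete.cases(co), , drop = FALSE]
    p <- p + geom_point(data = co,
                        aes(x = .data$longitude, y = .data$latitude),
                        colour = "darkgreen", size = 0.8, inherit.aes = FALSE)
  }
  if (!is.null(sites))
    p <- p + geom_point(data = sites, aes(x = .data$lon, y = .data$lat),
                        shape = 8, size = 3, colour = "black",
                        inherit.aes = FALSE)
  p
}

#' Map GBSSI genotypes
#'
#' Geolocated samples coloured by their genotype at one GBSSI locus,
#' mirroring the usual waxy-allele distribution maps.
#'
#' @param table a [SampleTable-class].
#' @param locus "S" or "L".
#' @return a ggplot object.
#' @export
plotGBSSIMap <- function(table, locus = c("S", "L")) {
  locus <- match.arg(locus)
  s <- sampleData(table)
  s$genotype <- if (locus == "S") s$gbssi_s else s$gbssi_l
  keep <- stats::complete.cases(s[c("latitude", "longitude")]) &
    !is.na(s$genotype)
  nSkip <- sum(!keep)
  if (nSkip) message(nSkip, " sample(s) skipped (no coordinates/genotype)")
  ggplot(s[keep, ], aes(x = .data$longitude, y = .data$latitude,
                        colour = .data$genotype)) +
    geom_point(size = 2) + coord_quickmap() + theme_minimal() +
    labs(x = "longitude", y = "latitude",
         colour = paste0("GBSSI-", locus))
}

#' Ancestry pie-chart map
#'
#' Draws each sample as a pie whose wedges are proportional to its ancestry
#' memberships (e.g. a Q matrix from external Bayesian clustering), the
#' standard idiom for mapping genepool assignments.
#'
#' @param coords data.frame(lat, lon), one row per sample.
#' @param q numeric matrix (samples x clusters) of memberships; rows are
#'   renormalised to 1.
#' @param radiusDeg pie radius in degrees.
#' @param nArc polygon vertices per full circle.
#' @return a ggplot object.
#' @export
plotAncestryPies <- function(coords, q, radiusDeg = 0.5, nArc = 36) {
  stopifnot(nrow(coords) == nrow(q))
  q <- q / rowSums(q)
  polys <- list()
  for (s in seq_len(nrow(q))) {
    ang <- 2 * pi * cumsum(c(0, q[s, ]))
    for (k in seq_len(ncol(q))) {
      th <- seq(ang[k], ang[k + 1],
                length.out = max(2, ceiling(nArc * q[s, k])))
      polys[[length(polys) + 1L]] <- data.frame(
        lon = coords$lon[s] + c(0, radiusDeg * sin(th)),
        lat = coords$lat[s] + c(0, radiusDeg * cos(th)),
        id = paste(s, k), cluster = factor(k))
    }
  }
  dat <- do.call(rbind, polys)
  ggplot(dat, aes(x = .data$lon, y = .data$lat, group = .data$id,
                  fill = .data$cluster)) +
    geom_polygon(colour = NA) + coord_quickmap() + theme_minimal() +
    labs(x = "longitude", y = "latitude", fill = "genepool")
}

#' Null-distribution plot for a site comparison
#'
#' Histogram of the permuted differences in origin correlations with the
#' observed difference marked, the standard visual for the permutation
#' test.
#'
#' @param cmp a [PermutationComparison-class].
#' @return a ggplot object.
#' @export
plotNullDistribution <- function(cmp) {
  stopifnot(is(cmp, "PermutationComparison"))
  dat <- data.frame(delta = cmp@nullDeltaR)
  ggplot(dat, aes(x = .data$delta)) +
    geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = cmp@observedDeltaR, colour = "red",
               linewidth = 1) +
    theme_minimal() +
    labs(x = expression(Delta * r~"(permuted)"), y = "count",
         title = sprintf("%s vs %s: p = %.3f", cmp@labels[1],
                         cmp@labels[2], cmp@pTwoTailed))
}
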