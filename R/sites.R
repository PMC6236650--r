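#' Reference coordinates of candidate origin sites
#'
#' Approximate locations of the early archaeological sites conventionally
#' compared as candidate sources of the broomcorn millet expansion:
#' Dadiwan (Qin'an County, Gansu), Xinglonggou (Aohan Banner, Chifeng,
#' Inner Mongolia) and Sokol'tsy (Southern Buh valley, Ukraine). The
#' coordinates are defaults taken from the archaeological literature at
#' roughly village-level precision; supply your own for finer work.
#'
#' @return data.frame(site, lat, lon).
#' @export
studySites <- function() {
  data.frame(
    site = c("Dadiwan", "Xinglonggou", "Sokol'tsy"),
    lat = c(35.00, 42.36, 48.80),
    lon = c(105.91, 120.10, 29.10),
    stringsAsFactors = FALSE)
}
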