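#' @name accessors
#' @title Accessors for the core classes
#' @description Slot access goes through these accessors, never through
#'   \code{@}.
#' @param x an object of the documented class.
#' @return The named component.
NULL

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))
#' @rdname accessors
#' @export
setGeneric("copiesPerSample", function(x) standardGeneric("copiesPerSample"))
#' @rdname accessors
#' @export
setGeneric("gridLats", function(x) standardGeneric("gridLats"))
#' @rdname accessors
#' @export
setGeneric("gridLons", function(x) standardGeneric("gridLons"))
#' @rdname accessors
#' @export
setGeneric("gridNodes", function(x) standardGeneric("gridNodes"))
#' @rdname accessors
#' @export
setGeneric("nKernels", function(x) standardGeneric("nKernels"))
#' @rdname accessors
#' @export
setGeneric("kernelCenters", function(x) standardGeneric("kernelCenters"))
#' @rdname accessors
#' @export
setGeneric("kernelMembers", function(x) standardGeneric("kernelMembers"))
#' @rdname accessors
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("observedDeltaR", function(x) standardGeneric("observedDeltaR"))
#' @rdname accessors
#' @export
setGeneric("nullDeltaR", function(x) standardGeneric("nullDeltaR"))

#' Best-supported origin node(s) of a correlation surface
#'
#' @param x an [OriginSurface-class].
#' @param ... unused.
#' @return data.frame of the node(s) attaining the most negative
#'   correlation (\code{lat}, \code{lon}, \code{r}).
#' @export
setGeneric("bestOrigin", function(x, ...) standardGeneric("bestOrigin"))
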