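#' @rdname CaExperiment-accessors
#' @export
setGeneric("caValues", function(x, ...) standardGeneric("caValues"))

#' @rdname CaExperiment-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname CaExperiment-accessors
#' @export
setGeneric("controlGenes", function(x) standardGeneric("controlGenes"))

#' @rdname StabilityRanking-accessors
#' @export
setGeneric("stabilityM", function(x) standardGeneric("stabilityM"))

#' @rdname StabilityRanking-accessors
#' @export
setGeneric("exclusionOrder", function(x) standardGeneric("exclusionOrder"))

#' @rdname PcaResult-accessors
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname PcaResult-accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname PcaResult-accessors
#' @export
setGeneric("markerPair", function(x) standardGeneric("markerPair"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("loadingFactors", function(x) standardGeneric("loadingFactors"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))
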