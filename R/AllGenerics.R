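#' @export
setGeneric("features", function(object, ...) standardGeneric("features"))

#' @export
setGeneric("sampleWeights", function(object, ...) standardGeneric("sampleWeights"))

#' @export
setGeneric("coords", function(object, ...) standardGeneric("coords"))

#' @export
setGeneric("biasValues", function(object, ...) standardGeneric("biasValues"))

#' @export
setGeneric("ctValues", function(object, ...) standardGeneric("ctValues"))

#' @export
setGeneric("frameTimes", function(object, ...) standardGeneric("frameTimes"))

#' @export
setGeneric("nSamples", function(object, ...) standardGeneric("nSamples"))

#' @export
setGeneric("mixtureMatrix", function(object, ...) standardGeneric("mixtureMatrix"))

#' @export
setGeneric("lossHistory", function(object, ...) standardGeneric("lossHistory"))

#' @export
setGeneric("fesValues", function(object, ...) standardGeneric("fesValues"))

#' @export
setGeneric("fesAxes", function(object, ...) standardGeneric("fesAxes"))
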