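#' @rdname SignalingNetwork-class
#' @param object,x a \code{SignalingNetwork}
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("biasTerms", function(x) standardGeneric("biasTerms"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("sourceNodes", function(x) standardGeneric("sourceNodes"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("sinkNodes", function(x) standardGeneric("sinkNodes"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PerturbationExperiment-class
#' @export
setGeneric("observationMatrix", function(x) standardGeneric("observationMatrix"))

#' @rdname PerturbationExperiment-class
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname PerturbationExperiment-class
#' @export
setGeneric("activationThresholds",
           function(x) standardGeneric("activationThresholds"))
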