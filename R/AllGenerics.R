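#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @rdname accessors
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("permPvalues", function(x) standardGeneric("permPvalues"))
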