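#' Sampling rate accessor
#' @param object An object with a sampling rate.
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EcgRecord", function(object) object@fs)

#' Record identifier accessor
#' @param object An object carrying a record id.
#' @return Character id.
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @rdname recordId
#' @export
setMethod("recordId", "EcgRecord", function(object) object@id)

#' Lead names accessor
#' @param object An [EcgRecord-class].
#' @return Character vector of lead names.
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))

#' @rdname leadNames
#' @export
setMethod("leadNames", "EcgRecord", function(object) object@leads)

#' Signal matrix accessor
#' @param object An [EcgRecord-class].
#' @return Numeric matrix (samples x leads), mV.
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "EcgRecord", function(object) object@signals)

#' Image list accessor
#' @param object A [LabeledImageSet-class].
#' @return List of integer image matrices.
#' @export
setGeneric("imageList", function(object) standardGeneric("imageList"))

#' @rdname imageList
#' @export
setMethod("imageList", "LabeledImageSet", function(object) object@images)

#' Image metadata accessor
#' @param object A [LabeledImageSet-class].
#' @return `data.frame` with id, class and provenance per image.
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))

#' @rdname imageMeta
#' @export
setMethod("imageMeta", "LabeledImageSet", function(object) object@meta)
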