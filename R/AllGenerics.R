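#' @rdname accessors
#' @export
setGeneric("schemaLabels", function(x) standardGeneric("schemaLabels"))

#' @rdname accessors
#' @export
setGeneric("corpusSchema", function(x) standardGeneric("corpusSchema"))

#' @rdname accessors
#' @export
setGeneric("messageIds", function(x) standardGeneric("messageIds"))

#' @rdname accessors
#' @export
setGeneric("messageText", function(x) standardGeneric("messageText"))

#' @rdname accessors
#' @export
setGeneric("messageLabels", function(x) standardGeneric("messageLabels"))

#' @rdname accessors
#' @export
setGeneric("nMessages", function(x) standardGeneric("nMessages"))

#' @rdname accessors
#' @export
setGeneric("encoderName", function(x) standardGeneric("encoderName"))

#' @rdname accessors
#' @export
setGeneric("embeddingIds", function(x) standardGeneric("embeddingIds"))

#' @rdname accessors
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname accessors
#' @export
setGeneric("predictionIds", function(x) standardGeneric("predictionIds"))

#' @rdname accessors
#' @export
setGeneric("predictionLabels",
           function(x) standardGeneric("predictionLabels"))

#' @rdname accessors
#' @export
setGeneric("predictionProbs", function(x) standardGeneric("predictionProbs"))

#' @rdname accessors
#' @export
setGeneric("predictionSource",
           function(x) standardGeneric("predictionSource"))

#' @rdname accessors
#' @export
setGeneric("agreedIds", function(x) standardGeneric("agreedIds"))

#' @rdname accessors
#' @export
setGeneric("disagreedIds", function(x) standardGeneric("disagreedIds"))

#' @rdname accessors
#' @export
setGeneric("consensusLabels", function(x) standardGeneric("consensusLabels"))
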