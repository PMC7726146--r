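#' @rdname accessors
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x, electrode) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x, ...) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("tStart", function(x) standardGeneric("tStart"))

#' @rdname accessors
#' @export
setGeneric("tStop", function(x) standardGeneric("tStop"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname map-accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname map-accessors
#' @export
setGeneric("moduleOf", function(x, electrodes) standardGeneric("moduleOf"))

#' @rdname map-accessors
#' @export
setGeneric("electrodesOf", function(x, module) standardGeneric("electrodesOf"))

#' @rdname map-accessors
#' @export
setGeneric("isControl", function(x, electrodes) standardGeneric("isControl"))

#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
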