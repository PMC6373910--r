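#' @rdname accessors
#' @export
setGeneric("deltaM", function(object) standardGeneric("deltaM"))

#' @rdname accessors
#' @export
setGeneric("momentValues", function(object) standardGeneric("momentValues"))

#' @rdname accessors
#' @export
setGeneric("optimalScale", function(object) standardGeneric("optimalScale"))

#' @rdname accessors
#' @export
setGeneric("scaleR", function(object) standardGeneric("scaleR"))

#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(object) standardGeneric("kernelMatrix"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("roiArea", function(object) standardGeneric("roiArea"))

#' @rdname accessors
#' @export
setGeneric("roiSource", function(object) standardGeneric("roiSource"))

#' @rdname accessors
#' @export
setGeneric("qcPass", function(object) standardGeneric("qcPass"))

#' @rdname accessors
#' @export
setGeneric("responderClass", function(object) standardGeneric("responderClass"))
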