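#' @include AllClasses.R
NULL

#' @rdname ProteinSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("labels")

#' @rdname ProteinSet-accessors
#' @export
setGeneric("labels<-", function(x, value) standardGeneric("labels<-"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("ssAnnotation", function(x) standardGeneric("ssAnnotation"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("ssAnnotation<-", function(x, value) standardGeneric("ssAnnotation<-"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("domainAnnotation", function(x) standardGeneric("domainAnnotation"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("domainAnnotation<-", function(x, value) standardGeneric("domainAnnotation<-"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname ProteinSet-accessors
#' @export
setGeneric("setName<-", function(x, value) standardGeneric("setName<-"))

#' @rdname flattenDim
#' @export
setGeneric("flattenDim", function(x) standardGeneric("flattenDim"))

#' @rdname setTransferMode
#' @export
setGeneric("setTransferMode", function(model, mode, seed = NULL)
  standardGeneric("setTransferMode"))

#' @rdname extractRepresentation
#' @export
setGeneric("extractRepresentation", function(model, x)
  standardGeneric("extractRepresentation"))
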