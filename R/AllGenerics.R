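#' @include AllClasses.R
NULL

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("pxPerCm", function(x) standardGeneric("pxPerCm"))

#' @export
setGeneric("depthCm", function(x) standardGeneric("depthCm"))

#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @export
setGeneric("muscle", function(x) standardGeneric("muscle"))

#' @export
setGeneric("areaCm2", function(x) standardGeneric("areaCm2"))

#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))
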