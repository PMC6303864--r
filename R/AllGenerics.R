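#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @export
setGeneric("mafFilter", function(x, threshold = 0.01) standardGeneric("mafFilter"))

#' @export
setGeneric("oneHotEncode", function(x, ...) standardGeneric("oneHotEncode"))

#' @export
setGeneric("tripleMap", function(x) standardGeneric("tripleMap"))

#' @export
setGeneric("indicators", function(x) standardGeneric("indicators"))

#' @export
setGeneric("trainIds", function(x, fold = NULL) standardGeneric("trainIds"))

#' @export
setGeneric("testIds", function(x, fold = NULL) standardGeneric("testIds"))

#' @export
setGeneric("mseTrace", function(x) standardGeneric("mseTrace"))

#' @export
setGeneric("maeTrace", function(x) standardGeneric("maeTrace"))

#' @export
setGeneric("burnIn", function(x) standardGeneric("burnIn"))

#' @export
setGeneric("effectTable", function(x, ...) standardGeneric("effectTable"))
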