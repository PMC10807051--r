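#' @include AllClasses.R
NULL

#' @export
setGeneric("edges", function(object, ...) standardGeneric("edges"))
#' @export
setGeneric("nodes", function(object, ...) standardGeneric("nodes"))
#' @export
setGeneric("compartments", function(object, ...) standardGeneric("compartments"))
#' @export
setGeneric("speciesTable", function(object, ...) standardGeneric("speciesTable"))
#' @export
setGeneric("geneTable", function(object, ...) standardGeneric("geneTable"))
#' @export
setGeneric("rateLaws", function(object, ...) standardGeneric("rateLaws"))
#' @export
setGeneric("tarTable", function(object, ...) standardGeneric("tarTable"))
#' @export
setGeneric("omicsTable", function(object, ...) standardGeneric("omicsTable"))
#' @export
setGeneric("modelCounts", function(object, ...) standardGeneric("modelCounts"))
#' @export
setGeneric("provenanceLog", function(object, ...) standardGeneric("provenanceLog"))
#' @export
setGeneric("tcTimes", function(object, ...) standardGeneric("tcTimes"))
#' @export
setGeneric("tcValues", function(object, ...) standardGeneric("tcValues"))
#' @export
setGeneric("fitTable", function(object, ...) standardGeneric("fitTable"))
#' @export
setGeneric("fitProfiles", function(object, ...) standardGeneric("fitProfiles"))
#' @export
setGeneric("screenTable", function(object, ...) standardGeneric("screenTable"))
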