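# Generics for the package's S4 accessors.

#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @export
setGeneric("lineNames", function(x) standardGeneric("lineNames"))

#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @export
setGeneric("alleleCodes", function(x) standardGeneric("alleleCodes"))

#' @export
setGeneric("cytoplasm", function(x) standardGeneric("cytoplasm"))

#' @export
setGeneric("perLineCV", function(x) standardGeneric("perLineCV"))

#' @export
setGeneric("perExperimentCV", function(x) standardGeneric("perExperimentCV"))

#' @export
setGeneric("gridPositions", function(x) standardGeneric("gridPositions"))

#' @export
setGeneric("alleleProbs", function(x) standardGeneric("alleleProbs"))

#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
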