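#' @import methods
NULL

#' @export
setGeneric("registryGroups", function(x) standardGeneric("registryGroups"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("radiomicsNames", function(x) standardGeneric("radiomicsNames"))

#' @export
setGeneric("sisnNames", function(x) standardGeneric("sisnNames"))

#' @export
setGeneric("sizeMM", function(x) standardGeneric("sizeMM"))

#' @export
setGeneric("semanticLabels", function(x) standardGeneric("semanticLabels"))

#' @export
setGeneric("cohortRegistry", function(x) standardGeneric("cohortRegistry"))

#' @export
setGeneric("computeSISN", function(x, ...) standardGeneric("computeSISN"))

#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
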