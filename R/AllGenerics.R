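#' @title Generics for FeatureExperiment accessors and operations
#' @name microexplore-generics
#' @keywords internal
NULL

#' @export
setGeneric("abundance", function(x, ...) standardGeneric("abundance"))
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @export
setGeneric("normalizedTotal", function(x) standardGeneric("normalizedTotal"))
#' @export
setGeneric("opHistory", function(x) standardGeneric("opHistory"))
#' @export
setGeneric("experimentType", function(x) standardGeneric("experimentType"))
#' @export
setGeneric("reorder")
#' @export
setGeneric("featureData<-", function(x, value) standardGeneric("featureData<-"))
#' @export
setGeneric("sampleData<-", function(x, value) standardGeneric("sampleData<-"))
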