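NULL

#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @export
setGeneric("organ", function(x) standardGeneric("organ"))

#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))

#' @export
setGeneric("conditionOf", function(x) standardGeneric("conditionOf"))

#' @export
setGeneric("meanCPM", function(x) standardGeneric("meanCPM"))

#' @export
setGeneric("standardizedProfiles", function(x) standardGeneric("standardizedProfiles"))

#' @export
setGeneric("zeroVariance", function(x) standardGeneric("zeroVariance"))

#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
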