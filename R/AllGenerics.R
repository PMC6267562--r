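#' @rdname SpacerSet-class
#' @param object,x a \linkS4class{SpacerSet} (or other object, per method)
#' @export
setGeneric("spacerInfo", function(x) standardGeneric("spacerInfo"))

#' @rdname SpacerSet-class
#' @export
setGeneric("spacerSeqs", function(x) standardGeneric("spacerSeqs"))

#' @rdname SpacerSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpacerSet-class
#' @export
setGeneric("nSpacers", function(x) standardGeneric("nSpacers"))

#' @rdname SpacerSet-class
#' @export
setGeneric("spacerIds", function(x) standardGeneric("spacerIds"))

#' @rdname SpacerClustering-class
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname SpacerClustering-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname SpacerClustering-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname SpacerClustering-class
#' @export
setGeneric("mismatchCutoff", function(x) standardGeneric("mismatchCutoff"))

#' @rdname ColorStore-class
#' @export
setGeneric("colorTable", function(x) standardGeneric("colorTable"))

#' @rdname StrainOrdering-class
#' @export
setGeneric("orderedSamples", function(x) standardGeneric("orderedSamples"))

#' @rdname StrainOrdering-class
#' @export
setGeneric("guideTree", function(x) standardGeneric("guideTree"))
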