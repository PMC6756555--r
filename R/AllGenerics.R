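#' @rdname CorrelationNetwork-class
#' @param x an object.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("rThreshold", function(x) standardGeneric("rThreshold"))

#' @rdname CommunityAssignment-class
#' @param x an object.
#' @export
setGeneric("communityMembership",
           function(x) standardGeneric("communityMembership"))

#' @rdname CommunityAssignment-class
#' @export
setGeneric("screeTable", function(x) standardGeneric("screeTable"))

#' @rdname CommunityAssignment-class
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname SwitchExperiment-class
#' @param x an object.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Switch genes of an analysis or planted truth
#' @param x a [SwitchAnalysis-class] or [PlantedTruth-class].
#' @return character vector of gene identifiers.
#' @export
setGeneric("switchGenes", function(x) standardGeneric("switchGenes"))

#' @rdname PlantedTruth-class
#' @param x an object.
#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("moduleOfGene", function(x) standardGeneric("moduleOfGene"))

#' @rdname SwitchAnalysis-class
#' @param x an object.
#' @export
setGeneric("differentialTable",
           function(x) standardGeneric("differentialTable"))

#' @rdname SwitchAnalysis-class
#' @export
setGeneric("cartography", function(x) standardGeneric("cartography"))

#' @rdname SwitchAnalysis-class
#' @export
setGeneric("network", function(x) standardGeneric("network"))

#' @rdname SwitchAnalysis-class
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))
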