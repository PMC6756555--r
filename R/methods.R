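#' @describeIn CorrelationNetwork-class gene identifiers of the nodes.
#' @export
setMethod("nodes", "CorrelationNetwork", function(x) x@nodes)

#' @describeIn CorrelationNetwork-class edge table (`node_a`, `node_b`, `r`).
#' @export
setMethod("edges", "CorrelationNetwork", function(x) x@edges)

#' @describeIn CorrelationNetwork-class the |r| cutoff used.
#' @export
setMethod("rThreshold", "CorrelationNetwork", function(x) x@rThreshold)

#' @describeIn CommunityAssignment-class named node -> community vector.
#' @export
setMethod("communityMembership", "CommunityAssignment",
          function(x) x@membership)

#' @describeIn CommunityAssignment-class candidate-k versus SSE table.
#' @export
setMethod("screeTable", "CommunityAssignment", function(x) x@scree)

#' @describeIn CommunityAssignment-class the selected number of communities.
#' @export
setMethod("chosenK", "CommunityAssignment", function(x) x@k)

#' @describeIn SwitchExperiment-class group factor (control/disease), named
#'   by sample.
#' @export
setMethod("sampleGroups", "SwitchExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @describeIn PlantedTruth-class planted switch genes.
#' @export
setMethod("switchGenes", "PlantedTruth", function(x) x@switchGenes)

#' @describeIn SwitchAnalysis-class genes called as switch genes.
#' @export
setMethod("switchGenes", "SwitchAnalysis", function(x)
  x@cartography$gene[x@cartography$is_switch])

#' @describeIn PlantedTruth-class genes carrying the planted group shift.
#' @export
setMethod("deGenes", "PlantedTruth", function(x) x@deGenes)

#' @describeIn PlantedTruth-class module index per gene (`NA` = none).
#' @export
setMethod("moduleOfGene", "PlantedTruth", function(x) x@moduleOfGene)

#' @describeIn SwitchAnalysis-class per-gene differential table.
#' @export
setMethod("differentialTable", "SwitchAnalysis", function(x) x@differential)

#' @describeIn SwitchAnalysis-class per-node cartography table.
#' @export
setMethod("cartography", "SwitchAnalysis", function(x) x@cartography)

#' @describeIn SwitchAnalysis-class the thresholded co-expression network.
#' @export
setMethod("network", "SwitchAnalysis", function(x) x@network)

#' @describeIn SwitchAnalysis-class the community assignment.
#' @export
setMethod("communities", "SwitchAnalysis", function(x) x@communities)

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  cat("  |r| threshold:", format(object@rThreshold, digits = 4), "\n")
  if (nrow(object@edges))
    cat("  negative-weight edges:", sum(object@edges$r < 0), "\n")
})

setMethod("show", "CommunityAssignment", function(object) {
  cat("CommunityAssignment: k =", object@k, "communities over",
      length(object@membership), "nodes\n")
  cat("  sizes:", paste(tabulate(object@membership, object@k),
                        collapse = ", "), "\n")
  cat("  scree evaluated at k =", paste(range(object@scree$k),
                                        collapse = ".."),
      "with", object@nReplicates, "replicates\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nModules, "modules x", object@genesPerModule,
      "genes,", object@nSwitch, "switch,", object@nNoiseGenes, "noise genes;",
      2L * object@nSamplesPerGroup, "samples\n")
  cat(sprintf("  de effect %.2f log2, loading %.2f, switch loading -%.2f, noise sd %.2f, seed %d\n",
              object@deLog2Effect, object@loading,
              object@switchNegativeLoading, object@noiseSd, object@seed))
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@moduleOfGene), "genes;",
      sum(!is.na(object@moduleOfGene)), "in modules;",
      length(object@switchGenes), "switch;",
      length(object@deGenes), "differential\n")
})

setMethod("show", "SwitchAnalysis", function(object) {
  cat("SwitchAnalysis\n")
  cat("  genes after expression filter:", nrow(object@experiment), "\n")
  cat("  genes retained by differential filter:",
      sum(object@differential$retained), "\n")
  cat("  network:", length(object@network@nodes), "nodes,",
      nrow(object@network@edges), "edges; k =", object@communities@k, "\n")
  sw <- object@cartography$gene[object@cartography$is_switch]
  cat("  switch genes:", length(sw), "\n")
  if (length(sw))
    cat("   ", paste(utils::head(sw, 10L), collapse = ", "),
        if (length(sw) > 10L) "...", "\n")
})
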