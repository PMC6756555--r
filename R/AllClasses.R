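#' @import methods
#' @importFrom stats setNames
NULL

#' Two-group expression experiment
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples matrix of log2-scale intensities together with a
#' disease/control group factor in `colData(x)$group`. The validity method
#' enforces the contract every downstream stage relies on: unique gene and
#' sample identifiers, fully finite values, and a group label for every
#' sample.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [switchExperiment()] for the user-facing constructor.
#' @export
setClass("SwitchExperiment", contains = "SummarizedExperiment")

.validSwitchExperiment <- function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("at least one assay is required")
  m <- SummarizedExperiment::assay(object)
  if (!is.numeric(m))
    msg <- c(msg, "expression values must be numeric")
  if (any(!is.finite(m)))
    msg <- c(msg, "expression values must be finite (impute or drop missing entries before construction)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- cd$group
    if (!is.factor(g) || !identical(levels(g), c("control", "disease")))
      msg <- c(msg, "group must be a factor with levels c('control', 'disease')")
    if (anyNA(g))
      msg <- c(msg, "every sample needs a group label")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SwitchExperiment", .validSwitchExperiment)

#' Signed Pearson co-expression network
#'
#' Undirected graph over retained genes. Edges carry the signed Pearson
#' correlation `r` as weight and every edge satisfies `|r| >= rThreshold`.
#' Genes left without any edge at the threshold are dropped at construction
#' (and reported), so every node has degree >= 1.
#'
#' @slot nodes character vector of gene identifiers (unique).
#' @slot edges data.frame with columns `node_a`, `node_b`, `r`.
#' @slot rThreshold numeric in (0, 1), the |r| cutoff used.
#' @export
setClass("CorrelationNetwork",
  representation(nodes = "character", edges = "data.frame",
                 rThreshold = "numeric"))

.validCorrelationNetwork <- function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("node_a", "node_b", "r") %in% colnames(e)))
    return("edges needs columns node_a, node_b, r")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (length(object@rThreshold) != 1L || object@rThreshold <= 0 ||
      object@rThreshold >= 1)
    msg <- c(msg, "rThreshold must be a single value in (0, 1)")
  if (nrow(e)) {
    if (any(e$node_a == e$node_b))
      msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
    if (any(abs(e$r) > 1))
      msg <- c(msg, "edge weights must lie in [-1, 1]")
    if (length(object@rThreshold) == 1L &&
        any(abs(e$r) < object@rThreshold - 1e-12))
      msg <- c(msg, "every edge must satisfy |r| >= rThreshold")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CorrelationNetwork", .validCorrelationNetwork)

#' Community assignment from replicated k-means
#'
#' @slot membership named integer vector, node -> community index in 1..k.
#' @slot k chosen number of communities.
#' @slot scree data.frame with columns `k` and `sse`: best-of-replicates
#'   within-cluster sum of squared errors per candidate k.
#' @slot nReplicates number of random restarts per candidate k.
#' @slot seed RNG seed the restarts were run under.
#' @export
setClass("CommunityAssignment",
  representation(membership = "integer", k = "integer", scree = "data.frame",
                 nReplicates = "integer", seed = "integer"))

.validCommunityAssignment <- function(object) {
  msg <- character()
  mem <- object@membership
  if (is.null(names(mem)) || anyDuplicated(names(mem)))
    msg <- c(msg, "membership must be named by unique node ids")
  if (length(mem) && (anyNA(mem) || any(mem < 1L) || any(mem > object@k)))
    msg <- c(msg, "membership values must lie in 1..k")
  if (nrow(object@scree) > 1L) {
    sse <- object@scree$sse[order(object@scree$k)]
    if (any(diff(sse) > 1e-8 * max(sse[1L], 1)))
      msg <- c(msg, "best-of-replicates SSE must be non-increasing in k")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CommunityAssignment", .validCommunityAssignment)

#' Parameters of the synthetic two-group expression generator
#'
#' See [generateDataset()] for the generative model. Defaults are the
#' package's reference simulation: 3 modules x 60 genes, 10 switch genes,
#' 50 background genes, 20 + 20 samples, a 2 log2-unit group effect,
#' module-factor loading 0.9, switch anti-loading 0.7 and noise sd 0.4.
#'
#' @slot nModules number of planted correlation modules.
#' @slot genesPerModule genes per module.
#' @slot nSwitch number of planted switch genes.
#' @slot nNoiseGenes background genes belonging to no module.
#' @slot nSamplesPerGroup samples per group (control and disease).
#' @slot deLog2Effect log2 group shift of differential genes.
#' @slot loading module-factor loading magnitude, in (0, 1].
#' @slot switchNegativeLoading magnitude of the negative loading of switch
#'   genes on every module factor, in (0, 1].
#' @slot noiseSd gene-level Gaussian noise sd (log2 units).
#' @slot baselineMean log2 intensity offset.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(nModules = "integer", genesPerModule = "integer",
                 nSwitch = "integer", nNoiseGenes = "integer",
                 nSamplesPerGroup = "integer", deLog2Effect = "numeric",
                 loading = "numeric", switchNegativeLoading = "numeric",
                 noiseSd = "numeric", baselineMean = "numeric",
                 seed = "integer"))

.validSyntheticSpec <- function(object) {
  bad <- function(field, test) if (test) field else NULL
  msg <- c(
    bad("nModules", object@nModules < 1L),
    bad("genesPerModule", object@genesPerModule < 1L),
    bad("nSwitch", object@nSwitch < 0L),
    bad("nNoiseGenes", object@nNoiseGenes < 0L),
    bad("nSamplesPerGroup", object@nSamplesPerGroup < 1L),
    bad("deLog2Effect", object@deLog2Effect < 0),
    bad("loading", object@loading <= 0 || object@loading > 1),
    bad("switchNegativeLoading",
        object@switchNegativeLoading <= 0 || object@switchNegativeLoading > 1),
    bad("noiseSd", object@noiseSd < 0))
  slots <- c("nModules", "genesPerModule", "nSwitch", "nNoiseGenes",
             "nSamplesPerGroup", "deLog2Effect", "loading",
             "switchNegativeLoading", "noiseSd", "baselineMean", "seed")
  nas <- slots[vapply(slots, function(s) anyNA(slot(object, s)), logical(1L))]
  msg <- c(msg, nas)
  if (length(msg))
    paste0("invalid field(s): ", paste(unique(msg), collapse = ", "))
  else TRUE
}
setValidity("SyntheticSpec", .validSyntheticSpec)

#' Ground truth of a synthetic dataset
#'
#' @slot moduleOfGene named integer vector; module index per gene, `NA` for
#'   genes in no module (switch and noise genes).
#' @slot deGenes gene ids carrying the group shift.
#' @slot switchGenes planted switch genes.
#' @slot spec the [SyntheticSpec-class] the dataset was generated from.
#' @export
setClass("PlantedTruth",
  representation(moduleOfGene = "integer", deGenes = "character",
                 switchGenes = "character", spec = "SyntheticSpec"))

.validPlantedTruth <- function(object) {
  msg <- character()
  genes <- names(object@moduleOfGene)
  if (is.null(genes) || anyDuplicated(genes))
    msg <- c(msg, "moduleOfGene must be named by unique gene ids")
  if (!all(object@deGenes %in% genes))
    msg <- c(msg, "deGenes must be a subset of all gene ids")
  if (!all(object@switchGenes %in% genes))
    msg <- c(msg, "switchGenes must be a subset of all gene ids")
  inModule <- genes[!is.na(object@moduleOfGene)]
  if (length(intersect(object@switchGenes, inModule)))
    msg <- c(msg, "switch genes must not belong to any module")
  if (length(msg)) msg else TRUE
}
setValidity("PlantedTruth", .validPlantedTruth)

#' Result of a full switch-gene analysis
#'
#' Bundle of every stage's output for one run of [runSwitchAnalysis()]:
#' the filtered experiment, the differential table, the thresholded
#' co-expression network, the k-means communities, the per-node cartography
#' (with switch calls) and the configuration used.
#'
#' @slot experiment the [SwitchExperiment-class] after low-expression
#'   filtering.
#' @slot differential data.frame, one row per gene (see [groupStats()]).
#' @slot network [CorrelationNetwork-class] over retained genes.
#' @slot communities [CommunityAssignment-class].
#' @slot cartography data.frame, one row per network node (see
#'   [computeCartography()] and [classifyNodes()]).
#' @slot config the configuration list (see [switchConfig()]).
#' @export
setClass("SwitchAnalysis",
  representation(experiment = "SwitchExperiment", differential = "data.frame",
                 network = "CorrelationNetwork",
                 communities = "CommunityAssignment",
                 cartography = "data.frame", config = "list"))
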