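#' Pipeline configuration
#'
#' Collects and validates every tunable of the analysis. One master `seed`
#' governs all stochastic stages through fixed per-stage substreams:
#' `seed + 1` calibrates the permutation correlation threshold, `seed + 2`
#' drives the k-means restarts and `seed + 3` the random removal curves.
#'
#' @param floorPercentile low-expression floor percentile
#'   ([filterLowExpression()]).
#' @param fcThreshold linear fold-change cutoff, >= 1 (typical range 2-4;
#'   regions with few differential genes may need 2-2.5).
#' @param fdrThreshold FDR cutoff in (0, 1].
#' @param rThreshold `"permutation"` or fixed numeric in (0, 1)
#'   ([buildCorrelationNetwork()]).
#' @param kRange candidate community counts ([kmeansCommunities()]).
#' @param nReplicates k-means restarts per candidate k.
#' @param elbowTol relative SSE-drop tolerance of the scree elbow.
#' @param k optional fixed community count overriding the elbow.
#' @param nSteps removal batches of the robustness curves.
#' @param nRandomRepeats random draws of the random removal curve.
#' @param seed master RNG seed.
#' @return validated configuration list of class `switchConfig`.
#' @export
switchConfig <- function(floorPercentile = 20, fcThreshold = 2,
                         fdrThreshold = 0.05, rThreshold = "permutation",
                         kRange = 2:15, nReplicates = 100, elbowTol = 0.05,
                         k = NULL, nSteps = 20, nRandomRepeats = 20,
                         seed = 1) {
  if (floorPercentile < 0 || floorPercentile >= 100)
    stop("floorPercentile must lie in [0, 100)")
  if (!is.numeric(fcThreshold) || fcThreshold < 1)
    stop("fcThreshold must be >= 1")
  if (fdrThreshold <= 0 || fdrThreshold > 1)
    stop("fdrThreshold must lie in (0, 1]")
  if (!identical(rThreshold, "permutation") &&
      (!is.numeric(rThreshold) || rThreshold <= 0 || rThreshold >= 1))
    stop("rThreshold must be 'permutation' or a number in (0, 1)")
  if (nSteps < 1L || nRandomRepeats < 1L || nReplicates < 1L)
    stop("nSteps, nRandomRepeats and nReplicates must be positive")
  structure(list(floorPercentile = floorPercentile,
                 fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
                 rThreshold = rThreshold, kRange = as.integer(kRange),
                 nReplicates = as.integer(nReplicates),
                 elbowTol = elbowTol, k = k, nSteps = as.integer(nSteps),
                 nRandomRepeats = as.integer(nRandomRepeats),
                 seed = as.integer(seed)),
            class = "switchConfig")
}

#' Run the switch-gene analysis on an expression experiment
#'
#' Executes, in order: low-expression filtering, differential analysis
#' (group means, fold-change, Welch p-values, BH FDR, retention), signed
#' Pearson network construction over the retained genes, replicated k-means
#' community detection, heat-cartography computation and node
#' classification.
#'
#' @param se a [SwitchExperiment-class].
#' @param config a [switchConfig()].
#' @return a [SwitchAnalysis-class].
#' @examples
#' sim <- generateDataset(syntheticSpec(seed = 1))
#' res <- runSwitchAnalysis(sim$experiment, switchConfig(seed = 1))
#' head(switchGenes(res))
#' @export
runSwitchAnalysis <- function(se, config = switchConfig()) {
  stopifnot(is(se, "SwitchExperiment"), inherits(config, "switchConfig"))
  filtered <- filterLowExpression(se, config$floorPercentile)
  dt <- differentialAnalysis(filtered, config$fcThreshold,
                             config$fdrThreshold)
  retained <- dt$gene[dt$retained]
  net <- buildCorrelationNetwork(filtered, genes = retained,
                                 rThreshold = config$rThreshold,
                                 seed = config$seed + 1L)
  kRange <- config$kRange[config$kRange <= length(net@nodes) - 1L]
  if (!length(kRange))
    stop("network too small for the configured kRange")
  comm <- kmeansCommunities(filtered, net, kRange = kRange,
                            nReplicates = config$nReplicates,
                            seed = config$seed + 2L,
                            elbowTol = config$elbowTol, k = config$k)
  cart <- classifyNodes(computeCartography(net, comm))
  new("SwitchAnalysis", experiment = filtered, differential = dt,
      network = net, communities = comm, cartography = cart,
      config = unclass(config))
}

#' Run the full pipeline from files and write all artifacts
#'
#' Reads an expression TSV plus group TSV (see [readExpression()]), runs
#' [runSwitchAnalysis()] and [robustnessAnalysis()], and writes to
#' `outputDir`: `differential.tsv`, `network_edges.tsv`, `cartography.tsv`,
#' `robustness.tsv`, `switch_genes.txt`, `scree.tsv` and a `manifest.json`
#' recording package version, configuration, seed and per-stage counts.
#' Identical input, configuration and seed reproduce identical artifacts.
#'
#' @param matrixPath genes x samples TSV (first column `gene`).
#' @param groupsPath two-column `sample`/`group` TSV.
#' @param outputDir directory for artifacts (created if missing).
#' @param config a [switchConfig()].
#' @return invisibly, the [SwitchAnalysis-class].
#' @export
runPipeline <- function(matrixPath, groupsPath, outputDir,
                        config = switchConfig()) {
  se <- readExpression(matrixPath, groupsPath)
  res <- runSwitchAnalysis(se, config)
  curves <- robustnessAnalysis(res@network, res@cartography,
                               nSteps = config$nSteps,
                               seed = config$seed + 3L,
                               nRandomRepeats = config$nRandomRepeats)
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  writeDifferential(res@differential, file.path(outputDir,
                                                "differential.tsv"))
  writeNetwork(res@network, file.path(outputDir, "network_edges.tsv"))
  writeCartography(res@cartography, file.path(outputDir, "cartography.tsv"))
  writeRobustness(curves, file.path(outputDir, "robustness.tsv"))
  writeLines(switchGenes(res), file.path(outputDir, "switch_genes.txt"))
  utils::write.table(res@communities@scree, file.path(outputDir,
                                                      "scree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "switchcart",
    version = as.character(utils::packageVersion("switchcart")),
    config = res@config[setdiff(names(res@config), "k")],
    k_fixed = if (is.null(res@config$k)) NA else res@config$k,
    seed = res@config$seed,
    counts = list(
      genes_input = nrow(se),
      genes_after_expression_filter = nrow(res@experiment),
      genes_retained = sum(res@differential$retained),
      network_nodes = length(res@network@nodes),
      network_edges = nrow(res@network@edges),
      communities = res@communities@k,
      switch_genes = length(switchGenes(res))),
    r_threshold_used = res@network@rThreshold)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(res)
}

#' Compare switch-gene sets across completed runs
#'
#' Reads `switch_genes.txt` from each run directory and reports exclusive
#' (UpSet) and pairwise (Venn) overlap counts via [overlapCounts()].
#'
#' @param runDirs named character vector of run output directories (names
#'   label the runs, e.g. brain regions); or a named list of character
#'   vectors of switch genes.
#' @return the [overlapCounts()] report.
#' @export
compareRegions <- function(runDirs) {
  if (is.list(runDirs)) {
    sets <- runDirs
  } else {
    if (is.null(names(runDirs)))
      names(runDirs) <- basename(runDirs)
    sets <- lapply(runDirs, function(d) {
      f <- file.path(d, "switch_genes.txt")
      if (!file.exists(f))
        stop("run '", d, "' has no switch_genes.txt")
      readLines(f)
    })
  }
  if (length(sets) < 2L) stop("need at least two runs to compare")
  overlapCounts(sets)
}

#' Precision and recall of switch-gene calls against planted truth
#'
#' @param called character vector of called switch genes (e.g.
#'   `switchGenes(analysis)`).
#' @param truth a [PlantedTruth-class] or character vector of true switch
#'   genes.
#' @return named numeric: `precision`, `recall` (`NaN` when undefined).
#' @export
switchPrecisionRecall <- function(called, truth) {
  if (is(truth, "PlantedTruth")) truth <- switchGenes(truth)
  tp <- length(intersect(called, truth))
  c(precision = tp / length(called), recall = tp / length(truth))
}
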