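#' Construct a synthetic-data specification
#'
#' Parameters of the two-group expression generator used throughout the
#' package's validation. The defaults define the reference simulation:
#' 3 correlation modules of 60 genes, 10 planted switch genes, 50 background
#' genes, 20 control + 20 disease samples, a 2 log2-unit differential effect,
#' factor loading 0.9, switch anti-loading 0.7, noise sd 0.4, baseline 8.
#'
#' @param nModules,genesPerModule,nSwitch,nNoiseGenes,nSamplesPerGroup
#'   integer counts; see [SyntheticSpec-class].
#' @param deLog2Effect log2 group shift applied to differential genes.
#' @param loading module-factor loading magnitude, in (0, 1].
#' @param switchNegativeLoading magnitude of the negative loading of switch
#'   genes on every module factor, in (0, 1].
#' @param noiseSd gene-level Gaussian noise sd.
#' @param baselineMean log2 intensity offset.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return a validated [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(nModules = 2, genesPerModule = 10, seed = 7)
#' @export
syntheticSpec <- function(nModules = 3, genesPerModule = 60, nSwitch = 10,
                          nNoiseGenes = 50, nSamplesPerGroup = 20,
                          deLog2Effect = 2, loading = 0.9,
                          switchNegativeLoading = 0.7, noiseSd = 0.4,
                          baselineMean = 8, seed = 1) {
  spec <- new("SyntheticSpec",
    nModules = as.integer(nModules),
    genesPerModule = as.integer(genesPerModule),
    nSwitch = as.integer(nSwitch),
    nNoiseGenes = as.integer(nNoiseGenes),
    nSamplesPerGroup = as.integer(nSamplesPerGroup),
    deLog2Effect = as.numeric(deLog2Effect),
    loading = as.numeric(loading),
    switchNegativeLoading = as.numeric(switchNegativeLoading),
    noiseSd = as.numeric(noiseSd),
    baselineMean = as.numeric(baselineMean),
    seed = as.integer(seed))
  validObject(spec)
  spec
}

#' Generate a two-group expression matrix with planted structure
#'
#' Generative model. For each module m a latent factor f_m is drawn per
#' sample from N(0, 1). A gene g in module m has expression
#'
#'   baselineMean + loading * f_m(sample)
#'     + deLog2Effect * \[sample is disease\] + eps,   eps ~ N(0, noiseSd^2).
#'
#' Every module member is a differential gene, so whole modules survive the
#' fold-change filter. Planted switch genes belong to no module and load
#' negatively on every module factor, moving in the opposite direction to
#' the modules between the groups:
#'
#'   baselineMean - switchNegativeLoading * sum_m f_m(sample)
#'     - deLog2Effect * \[sample is disease\] + eps.
#'
#' The opposite-sign group shift keeps switch genes past the fold-change
#' filter while making their pooled-sample correlation with module members
#' negative — the fight-club geometry the cartography stage detects. Noise
#' genes are baselineMean + eps only and carry no group effect.
#'
#' A single RNG stream seeded with `spec@seed` is consumed in a documented
#' order — (1) the nModules x nSamples factor matrix, drawn module by
#' module, then (2) the gene x sample noise matrix, drawn gene by gene in
#' output row order — so the draws for early genes do not change if later
#' genes are added.
#'
#' Gene ids are `M<m>_G<j>` for module members, `SW_<j>` for switch genes
#' and `NOISE_<j>` for background genes; samples are `CTRL_<i>` then
#' `AD_<i>` (controls first).
#'
#' @param spec a [SyntheticSpec-class], e.g. from [syntheticSpec()].
#' @return a list with elements `experiment` (a [SwitchExperiment-class])
#'   and `truth` (a [PlantedTruth-class]).
#' @examples
#' sim <- generateDataset(syntheticSpec(nModules = 2, genesPerModule = 8,
#'                                      nSwitch = 2, nNoiseGenes = 5,
#'                                      nSamplesPerGroup = 6, seed = 3))
#' dim(sim$experiment)
#' switchGenes(sim$truth)
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)

  nMod <- spec@nModules
  gpm <- spec@genesPerModule
  nPerGroup <- spec@nSamplesPerGroup
  nSamples <- 2L * nPerGroup
  nGenes <- nMod * gpm + spec@nSwitch + spec@nNoiseGenes

  moduleGenes <- unlist(lapply(seq_len(nMod), function(m)
    sprintf("M%d_G%d", m, seq_len(gpm))), use.names = FALSE)
  switchIds <- if (spec@nSwitch) sprintf("SW_%d", seq_len(spec@nSwitch))
               else character()
  noiseIds <- if (spec@nNoiseGenes) sprintf("NOISE_%d",
                                            seq_len(spec@nNoiseGenes))
              else character()
  geneIds <- c(moduleGenes, switchIds, noiseIds)
  sampleIds <- c(sprintf("CTRL_%d", seq_len(nPerGroup)),
                 sprintf("AD_%d", seq_len(nPerGroup)))
  disease <- rep(c(0, 1), each = nPerGroup)

  set.seed(spec@seed)
  # (1) module factors, module-major
  factors <- matrix(stats::rnorm(nMod * nSamples), nrow = nMod, byrow = TRUE)
  # (2) per-gene noise, row order = output order
  noise <- matrix(if (spec@noiseSd > 0)
                    stats::rnorm(nGenes * nSamples, sd = spec@noiseSd)
                  else 0,
                  nrow = nGenes, ncol = nSamples, byrow = TRUE)

  signal <- matrix(spec@baselineMean, nrow = nGenes, ncol = nSamples)
  moduleIdx <- rep(seq_len(nMod), each = gpm)
  for (i in seq_along(moduleGenes)) {
    m <- moduleIdx[i]
    signal[i, ] <- signal[i, ] + spec@loading * factors[m, ] +
      spec@deLog2Effect * disease
  }
  if (spec@nSwitch) {
    foreign <- -spec@switchNegativeLoading * colSums(factors)
    for (j in seq_len(spec@nSwitch)) {
      i <- nMod * gpm + j
      signal[i, ] <- signal[i, ] + foreign - spec@deLog2Effect * disease
    }
  }
  values <- signal + noise
  dimnames(values) <- list(geneIds, sampleIds)

  se <- switchExperiment(values,
    setNames(rep(c("control", "disease"), each = nPerGroup), sampleIds))

  moduleOf <- setNames(rep(NA_integer_, nGenes), geneIds)
  moduleOf[moduleGenes] <- moduleIdx
  truth <- new("PlantedTruth",
    moduleOfGene = moduleOf,
    deGenes = c(moduleGenes, switchIds),
    switchGenes = switchIds,
    spec = spec)
  validObject(truth)

  list(experiment = se, truth = truth)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the expression matrix as TSV (first column `gene`, header row of
#' sample ids), a two-column `sample`/`group` TSV, and the planted truth as
#' JSON.
#'
#' @param sim result of [generateDataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written (`matrix`, `groups`, `truth`).
#' @export
writeDataset <- function(sim, dir) {
  stopifnot(is.list(sim), is(sim$experiment, "SwitchExperiment"),
            is(sim$truth, "PlantedTruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "expression.tsv"),
                groups = file.path(dir, "groups.tsv"),
                truth = file.path(dir, "truth.json"))
  writeExpression(sim$experiment, paths$matrix, paths$groups)
  spec <- sim$truth@spec
  truthList <- list(
    module_of_gene = as.list(sim$truth@moduleOfGene),
    de_genes = sim$truth@deGenes,
    switch_genes = sim$truth@switchGenes,
    spec = list(n_modules = spec@nModules,
                genes_per_module = spec@genesPerModule,
                n_switch = spec@nSwitch,
                n_noise_genes = spec@nNoiseGenes,
                n_samples_per_group = spec@nSamplesPerGroup,
                de_log2_effect = spec@deLog2Effect,
                loading = spec@loading,
                switch_negative_loading = spec@switchNegativeLoading,
                noise_sd = spec@noiseSd,
                baseline_mean = spec@baselineMean,
                seed = spec@seed))
  jsonlite::write_json(truthList, paths$truth, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}
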