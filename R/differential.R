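.groupMatrices <- function(x) {
  g <- sampleGroups(x)
  m <- SummarizedExperiment::assay(x)
  list(disease = m[, g == "disease", drop = FALSE],
       control = m[, g == "control", drop = FALSE])
}

#' Per-gene group means and linear fold-change
#'
#' Computes mean log2 expression per group and the linear fold-change
#' `2^(mean_disease - mean_control)`. Up- and down-regulation are treated
#' symmetrically at filtering time via `max(fc, 1/fc)` (see
#' [selectGenes()]).
#'
#' @param x a [SwitchExperiment-class] with at least two samples per group.
#' @return data.frame with columns `gene`, `mean_disease`, `mean_control`,
#'   `linear_fc`.
#' @export
groupStats <- function(x) {
  gm <- .groupMatrices(x)
  if (ncol(gm$disease) < 2L || ncol(gm$control) < 2L)
    stop("each group needs at least 2 samples")
  md <- rowMeans(gm$disease)
  mc <- rowMeans(gm$control)
  data.frame(gene = rownames(x), mean_disease = md, mean_control = mc,
             linear_fc = 2^(md - mc), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene Welch t-test p-values
#'
#' Two-sided Welch (unequal-variance) t-test on log2 values, vectorised over
#' genes. Degenerate genes with zero variance in both groups get p = 1 when
#' the group means are equal and p = 0 when they differ (a documented
#' convention: the data are then noiseless, so any mean difference is
#' unambiguous).
#'
#' @param x a [SwitchExperiment-class] with at least two samples per group.
#' @return numeric vector of p-values, named by gene.
#' @export
welchPvalues <- function(x) {
  gm <- .groupMatrices(x)
  n1 <- ncol(gm$disease); n2 <- ncol(gm$control)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples")
  m1 <- rowMeans(gm$disease); m2 <- rowMeans(gm$control)
  v1 <- rowSums((gm$disease - m1)^2) / (n1 - 1L)
  v2 <- rowSums((gm$control - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  setNames(p, rownames(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1 and returned in
#' the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values (same length/names).
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assemble the per-gene differential table
#'
#' Runs [groupStats()], [welchPvalues()] and [bhAdjust()] and flags retained
#' genes with [selectGenes()].
#'
#' @param x a [SwitchExperiment-class].
#' @param fcThreshold linear fold-change cutoff (>= 1); a gene passes when
#'   `max(fc, 1/fc) >= fcThreshold`.
#' @param fdrThreshold FDR cutoff in (0, 1].
#' @return data.frame with columns `gene`, `mean_disease`, `mean_control`,
#'   `linear_fc`, `p_value`, `fdr`, `retained`.
#' @export
differentialAnalysis <- function(x, fcThreshold = 2, fdrThreshold = 0.05) {
  dt <- groupStats(x)
  dt$p_value <- unname(welchPvalues(x))
  dt$fdr <- bhAdjust(dt$p_value)
  dt$retained <- FALSE
  dt$retained[dt$gene %in% selectGenes(dt, fcThreshold, fdrThreshold)] <- TRUE
  dt
}

#' Threshold-based gene retention
#'
#' Retains genes with `max(linear_fc, 1/linear_fc) >= fcThreshold` and
#' `fdr <= fdrThreshold`, in input order.
#'
#' @param dt differential table with columns `gene`, `linear_fc`, `fdr`.
#' @param fcThreshold linear fold-change cutoff, >= 1.
#' @param fdrThreshold FDR cutoff in (0, 1].
#' @return character vector of retained gene ids.
#' @export
selectGenes <- function(dt, fcThreshold = 2, fdrThreshold = 0.05) {
  if (fcThreshold < 1)
    stop("fcThreshold must be >= 1")
  if (fdrThreshold <= 0 || fdrThreshold > 1)
    stop("fdrThreshold must lie in (0, 1]")
  keep <- pmax(dt$linear_fc, 1 / dt$linear_fc) >= fcThreshold &
    dt$fdr <= fdrThreshold
  retained <- dt$gene[keep]
  if (!length(retained))
    stop("no gene passes fcThreshold = ", fcThreshold, " and fdrThreshold = ",
         fdrThreshold, "; consider lowering the fold-change threshold")
  message(length(retained), " of ", nrow(dt),
          " genes retained by the differential filter")
  retained
}

#' Write a differential table as TSV
#' @param dt result of [differentialAnalysis()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDifferential <- function(dt, path) {
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
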