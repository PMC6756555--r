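#' Gene-set collection against a universe
#'
#' @param sets named list of character vectors (set name -> gene symbols),
#'   e.g. from [readGmt()].
#' @param universe character vector of all assayable gene symbols (e.g. all
#'   genes on the platform after probe collapse).
#' @return list with elements `sets` (each intersected metadata kept as-is)
#'   and `universe`, validated: non-empty sets, every set intersecting the
#'   universe.
#' @export
geneSetCollection <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) > 0L, length(universe) > 0L)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  universe <- unique(as.character(universe))
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  inUniv <- vapply(sets, function(s) length(intersect(s, universe)) > 0L,
                   logical(1L))
  if (!all(inUniv))
    stop("gene set(s) disjoint from the universe: ",
         paste(names(sets)[!inUniv], collapse = ", "))
  list(sets = lapply(sets, unique), universe = universe)
}

#' Read a GMT gene-set file
#' @param path path to a GMT file (set name, description, then genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test per set: the probability of
#' observing at least the seen overlap between the query and the set when
#' drawing `|query|` genes from the universe. P-values are BH-adjusted
#' across sets. With `ease = TRUE` one gene is subtracted from the overlap
#' before the tail computation (the conservative EASE-style variant used by
#' popular annotation servers).
#'
#' @param query character vector of gene symbols (e.g. switch genes). Genes
#'   outside the universe are dropped with a warning.
#' @param gsc a [geneSetCollection()].
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05, on the unadjusted p-value).
#' @param ease use the EASE-style overlap - 1 tail?
#' @return data.frame sorted by p-value with columns `set_name`,
#'   `overlap_count`, `query_size`, `set_size`, `universe_size`,
#'   `fold_enrichment`, `p_value`, `fdr`, `significant`.
#' @export
hypergeometricEnrichment <- function(query, gsc, alpha = 0.05,
                                     ease = FALSE) {
  universe <- gsc$universe
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop("query is empty after intersecting with the universe")
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(gsc$sets), function(nm) {
    s <- intersect(gsc$sets[[nm]], universe)
    ov <- length(intersect(query, s))
    eff <- if (ease) max(ov - 1L, 0L) else ov
    p <- stats::phyper(eff - 1L, length(s), N - length(s), q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = ov, query_size = q,
               set_size = length(s), universe_size = N,
               fold_enrichment = (ov / q) / (length(s) / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p_value)
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Exclusive and pairwise overlaps between named gene sets
#'
#' Computes both reporting conventions for multi-set comparisons: the
#' 2^n - 1 exclusive intersection counts (UpSet semantics: each gene counts
#' toward exactly the combination of sets it belongs to) and the pairwise
#' total overlaps (Venn semantics).
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `exclusive` (data.frame `combination`, `degree`,
#'   `count`, combinations joined by `&`, sorted by decreasing count) and
#'   `pairwise` (symmetric integer matrix of total intersections; diagonal
#'   = set sizes).
#' @export
overlapCounts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nms <- names(sets)
  n <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0L), 0L, n, dimnames = list(NULL, nms))
  member <- matrix(member, ncol = n, dimnames = list(NULL, nms))
  patterns <- apply(member, 1L, function(b) paste(nms[b], collapse = "&"))
  allPatterns <- unlist(lapply(seq_len(n), function(d)
    utils::combn(nms, d, paste, collapse = "&")), use.names = FALSE)
  counts <- table(factor(patterns, levels = allPatterns))
  exclusive <- data.frame(combination = allPatterns,
                          degree = lengths(strsplit(allPatterns, "&",
                                                    fixed = TRUE)),
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
  exclusive <- exclusive[order(-exclusive$count, exclusive$degree,
                               exclusive$combination), , drop = FALSE]
  rownames(exclusive) <- NULL
  pairwise <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n))
    for (j in seq_len(n))
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(exclusive = exclusive, pairwise = pairwise)
}

#' Filter a TF-target edge table
#'
#' Keeps regulator-target edges passing the BETA-minus style filters —
#' ChIP peak intensity signal below 500 and predicted regulatory potential
#' score below 1 (both strict) — and drops duplicate (tf, target) pairs.
#'
#' @param edges data.frame with columns `tf`, `target`, `peak_intensity`,
#'   `regulatory_potential`.
#' @param maxPeakIntensity strict upper bound on peak intensity
#'   (default 500).
#' @param maxRegulatoryPotential strict upper bound on regulatory potential
#'   (default 1).
#' @return filtered, deduplicated data.frame (subset of the input rows).
#' @export
filterTfEdges <- function(edges, maxPeakIntensity = 500,
                          maxRegulatoryPotential = 1) {
  need <- c("tf", "target", "peak_intensity", "regulatory_potential")
  missing <- setdiff(need, colnames(edges))
  if (length(missing))
    stop("edge table is missing column(s): ",
         paste(missing, collapse = ", "))
  keep <- edges$peak_intensity < maxPeakIntensity &
    edges$regulatory_potential < maxRegulatoryPotential
  out <- edges[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("tf", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank transcription factors over a query gene set
#'
#' Builds the bipartite TF-target graph induced by the query genes (edges
#' whose target is in the query) and ranks TFs by degree — the number of
#' distinct query targets — descending, breaking ties by betweenness
#' centrality on that graph (descending), then by symbol.
#'
#' @param edges filtered TF-target edge table ([filterTfEdges()]).
#' @param query character vector of gene symbols.
#' @return data.frame with columns `tf`, `degree`, `betweenness`, `rank`;
#'   empty (with a warning) when no edge touches the query.
#' @export
rankTfs <- function(edges, query) {
  stopifnot(length(query) > 0L)
  ed <- edges[edges$target %in% query, , drop = FALSE]
  if (!nrow(ed)) {
    warning("no TF-target edge touches the query; empty ranking")
    return(data.frame(tf = character(), degree = integer(),
                      betweenness = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(ed[, c("tf", "target")],
                                     directed = FALSE)
  btw <- igraph::betweenness(g, weights = NA)
  tfs <- sort(unique(ed$tf))
  degree <- vapply(tfs, function(tf)
    length(unique(ed$target[ed$tf == tf])), integer(1L))
  out <- data.frame(tf = tfs, degree = degree,
                    betweenness = unname(btw[tfs]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$betweenness, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a TF-target edge TSV
#' @param path TSV with columns `tf`, `target`, `peak_intensity`,
#'   `regulatory_potential`.
#' @return data.frame.
#' @export
readTfEdges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
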