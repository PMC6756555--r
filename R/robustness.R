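#' Average shortest path of an unweighted network
#'
#' Mean of the unweighted shortest-path lengths over all connected ordered
#' node pairs; pairs in different components are excluded from the average,
#' which keeps the statistic finite as node removal fragments the graph.
#' A network with a single node (or no connected pair) has average shortest
#' path 0 by convention.
#'
#' @param net a [CorrelationNetwork-class] or an igraph graph.
#' @param nodes optional node subset (induced subgraph).
#' @return non-negative real.
#' @export
averageShortestPath <- function(net, nodes = NULL) {
  g <- if (is(net, "CorrelationNetwork")) asIgraph(net, nodes) else net
  if (igraph::vcount(g) == 0L) stop("empty network")
  if (igraph::vcount(g) == 1L) return(0)
  d <- igraph::distances(g, weights = NA)
  finite <- is.finite(d) & d > 0
  if (!any(finite)) return(0)
  mean(d[finite])
}

.removalCategories <- c("total hubs", "party hubs", "date hubs",
                        "fight-club hubs", "switch genes", "random")

.categoryMembers <- function(cart, category) {
  switch(category,
    "total hubs" = cart$gene[cart$is_hub],
    "party hubs" = cart$gene[cart$hub_class == "party"],
    "date hubs" = cart$gene[cart$hub_class == "date"],
    "fight-club hubs" = cart$gene[cart$hub_class == "fight-club"],
    "switch genes" = cart$gene[cart$is_switch],
    "random" = cart$gene,
    stop("unknown category: ", category))
}

#' Average-shortest-path curve under cumulative node removal
#'
#' Removes, in decreasing-degree order within the chosen category (ties
#' broken by node id), a total of `nRemove` nodes — by construction the
#' number of switch genes, so every category's curve spans the same removal
#' fractions — in `nSteps` equal batches, recomputing the average shortest
#' path after each batch. The `random` category draws `nRandomRepeats`
#' uniform node sets of the same size and reports each repeat (repeat 0 is
#' the per-step mean across repeats).
#'
#' @param net a [CorrelationNetwork-class].
#' @param cart classified cartography table ([classifyNodes()]).
#' @param category one of "total hubs", "party hubs", "date hubs",
#'   "fight-club hubs", "switch genes", "random".
#' @param nSteps number of removal batches (default 20).
#' @param seed RNG seed (random category).
#' @param nRemove total nodes to remove; defaults to the number of switch
#'   genes in `cart`.
#' @param nRandomRepeats random draws averaged for the `random` category.
#' @return data.frame with columns `category`, `fraction_removed`,
#'   `avg_shortest_path`, `repeat_index`; the first row of each repeat is
#'   the unperturbed baseline at fraction 0.
#' @export
removalCurve <- function(net, cart, category, nSteps = 20, seed = 1,
                         nRemove = NULL, nRandomRepeats = 20) {
  category <- match.arg(category, .removalCategories)
  stopifnot(nSteps >= 1L)
  if (is.null(nRemove)) nRemove <- sum(cart$is_switch)
  nNodes <- length(net@nodes)
  baseline <- averageShortestPath(net)
  if (nRemove == 0L) {
    warning("no nodes to remove (empty switch set); returning baseline only")
    return(data.frame(category = category, fraction_removed = 0,
                      avg_shortest_path = baseline, repeat_index = 0L,
                      stringsAsFactors = FALSE))
  }
  members <- intersect(.categoryMembers(cart, category), net@nodes)
  if (category != "random" && !length(members)) {
    warning("category '", category, "' is empty; returning baseline only")
    return(data.frame(category = category, fraction_removed = 0,
                      avg_shortest_path = baseline, repeat_index = 0L,
                      stringsAsFactors = FALSE))
  }
  ord <- function(ids) {
    d <- setNames(cart$degree, cart$gene)[ids]
    ids[order(-d, ids)]
  }
  batchEnds <- unique(round(seq_len(nSteps) / nSteps * nRemove))
  batchEnds <- batchEnds[batchEnds >= 1L]

  curveFor <- function(removalOrder, repIdx) {
    ends <- pmin(batchEnds, length(removalOrder))
    frac <- c(0, ends / nNodes)
    asp <- c(baseline, vapply(ends, function(e)
      averageShortestPath(net, setdiff(net@nodes, removalOrder[seq_len(e)])),
      numeric(1L)))
    keep <- !duplicated(frac)
    data.frame(category = category, fraction_removed = frac[keep],
               avg_shortest_path = asp[keep], repeat_index = repIdx,
               stringsAsFactors = FALSE)
  }

  if (category == "random") {
    set.seed(seed)
    reps <- lapply(seq_len(nRandomRepeats), function(rr)
      curveFor(sample(net@nodes, min(nRemove, nNodes - 1L)), rr))
    all <- do.call(rbind, reps)
    avg <- stats::aggregate(avg_shortest_path ~ fraction_removed, all, mean)
    rbind(data.frame(category = category,
                     fraction_removed = avg$fraction_removed,
                     avg_shortest_path = avg$avg_shortest_path,
                     repeat_index = 0L, stringsAsFactors = FALSE),
          all)
  } else {
    if (length(members) < nRemove)
      message("category '", category, "' has ", length(members),
              " member(s); removal truncated at that count")
    curveFor(ord(members), 0L)
  }
}

#' Removal curves for every node category
#'
#' Runs [removalCurve()] for all six categories on the same network, so the
#' curves share the same baseline point and removal budget.
#'
#' @inheritParams removalCurve
#' @return long-format data.frame (rows of all categories' curves).
#' @export
robustnessAnalysis <- function(net, cart, nSteps = 20, seed = 1,
                               nRandomRepeats = 20) {
  do.call(rbind, lapply(.removalCategories, function(cat)
    suppressWarnings(removalCurve(net, cart, cat, nSteps = nSteps,
                                  seed = seed,
                                  nRandomRepeats = nRandomRepeats))))
}

#' Area under a removal curve
#'
#' Trapezoidal area of average shortest path over removed fraction; a
#' larger area than the random curve's means the targeted removal degrades
#' the network more.
#'
#' @param curve one repeat of a [removalCurve()] result.
#' @return non-negative real.
#' @export
curveAuc <- function(curve) {
  o <- order(curve$fraction_removed)
  x <- curve$fraction_removed[o]
  y <- curve$avg_shortest_path[o]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Write robustness curves as long-format TSV
#' @param curves result of [robustnessAnalysis()] or [removalCurve()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRobustness <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
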