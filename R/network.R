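#' Permutation-based |r| threshold
#'
#' Estimates the co-expression significance cutoff as the `quantile`-th
#' percentile of |Pearson r| over `nPairs` randomly sampled gene pairs in
#' which one profile is randomly permuted across samples — a null that
#' destroys the gene-gene correlation while keeping each gene's marginal
#' distribution.
#'
#' @param m numeric genes x samples matrix.
#' @param nPairs number of gene pairs sampled (default 10000).
#' @param quantile null quantile of |r| used as threshold (default 0.999).
#' @param seed RNG seed.
#' @return single numeric threshold in (0, 1).
#' @export
permutationRThreshold <- function(m, nPairs = 10000, quantile = 0.999,
                                  seed = 1) {
  stopifnot(nrow(m) >= 2L, ncol(m) >= 4L)
  set.seed(seed)
  n <- ncol(m)
  z <- m - rowMeans(m)
  sds <- sqrt(rowSums(z^2))
  ok <- which(sds > 0)
  if (length(ok) < 2L) stop("need at least two genes with nonzero variance")
  z <- z[ok, , drop = FALSE] / sds[ok]
  i <- sample.int(nrow(z), nPairs, replace = TRUE)
  j <- sample.int(nrow(z) - 1L, nPairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over other genes
  r <- numeric(nPairs)
  for (p in seq_len(nPairs))
    r[p] <- sum(z[i[p], ] * z[j[p], sample.int(n)])
  thr <- stats::quantile(abs(r), quantile, names = FALSE)
  min(max(thr, 1e-6), 1 - 1e-6)
}

#' Build the signed Pearson co-expression network
#'
#' Pearson correlation between gene expression profiles is computed across
#' ALL samples, both groups pooled: pooling is what turns opposite
#' disease/control movements into negative correlations, the signal the
#' switch-gene criteria rely on. An edge is kept iff `|r| >= rThreshold`
#' (anti-correlated pairs are kept, with negative weight). Genes with zero
#' variance are excluded with a warning; genes left without any edge are
#' dropped and reported.
#'
#' @param x a [SwitchExperiment-class] (or plain genes x samples matrix).
#' @param genes optional subset of gene ids to use (e.g. the retained genes
#'   of [differentialAnalysis()]).
#' @param rThreshold numeric |r| cutoff in (0, 1), or `"permutation"` to
#'   calibrate it with [permutationRThreshold()].
#' @param seed RNG seed used when `rThreshold = "permutation"`.
#' @param nPairs,quantile passed to [permutationRThreshold()].
#' @return a [CorrelationNetwork-class].
#' @export
buildCorrelationNetwork <- function(x, genes = NULL,
                                    rThreshold = "permutation", seed = 1,
                                    nPairs = 10000, quantile = 0.999) {
  m <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
       else as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("unknown gene(s): ", paste(utils::head(missing, 5L),
                                      collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need at least 3 genes to build a network")
  if (ncol(m) < 4L) stop("need at least 4 samples to build a network")
  vars <- apply(m, 1L, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0),
            " zero-variance gene(s) excluded from the network")
    m <- m[vars > 0, , drop = FALSE]
  }
  if (identical(rThreshold, "permutation"))
    rThreshold <- permutationRThreshold(m, nPairs = nPairs,
                                        quantile = quantile, seed = seed)
  if (!is.numeric(rThreshold) || rThreshold <= 0 || rThreshold >= 1)
    stop("rThreshold must be 'permutation' or a number in (0, 1)")
  cc <- stats::cor(t(m))
  idx <- which(upper.tri(cc) & abs(cc) >= rThreshold, arr.ind = TRUE)
  if (!nrow(idx))
    stop("no gene pair reaches |r| >= ", format(rThreshold, digits = 4),
         "; consider a lower threshold")
  ed <- data.frame(node_a = rownames(cc)[idx[, 1L]],
                   node_b = rownames(cc)[idx[, 2L]],
                   r = cc[idx], stringsAsFactors = FALSE)
  connected <- sort(unique(c(ed$node_a, ed$node_b)))
  isolated <- setdiff(rownames(m), connected)
  if (length(isolated))
    message(length(isolated), " isolated gene(s) dropped from the network")
  keep <- rownames(m)[rownames(m) %in% connected]  # original order
  net <- new("CorrelationNetwork", nodes = keep, edges = ed,
             rThreshold = rThreshold)
  validObject(net)
  net
}

#' Convert a CorrelationNetwork to an igraph graph
#' @param net a [CorrelationNetwork-class].
#' @param nodes optional node subset (induced subgraph).
#' @return an undirected igraph graph with edge attribute `r`.
#' @export
asIgraph <- function(net, nodes = NULL) {
  if (is.null(nodes)) nodes <- net@nodes
  ed <- net@edges[net@edges$node_a %in% nodes &
                    net@edges$node_b %in% nodes, , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Find network communities by replicated k-means
#'
#' Feature vectors are the per-gene z-scored expression profiles of the
#' network nodes. For every candidate k the clustering is restarted
#' `nReplicates` times from fresh random centroids and the configuration
#' with the lowest within-cluster sum of squared errors (SSE) is kept; the
#' SSE-versus-k scree is then used to choose k at the elbow: the smallest k
#' whose relative SSE drop to k + 1 falls below `elbowTol` (default 5%),
#' or the first k at which the SSE vanishes.
#'
#' @param x the [SwitchExperiment-class] (or matrix) the network was built
#'   from.
#' @param net a [CorrelationNetwork-class].
#' @param kRange candidate community counts; must lie within
#'   \[2, number of nodes - 1\]. Candidates above the number of distinct
#'   node profiles are dropped (k-means needs distinct centroids).
#' @param nReplicates random restarts per candidate (default 100).
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @param elbowTol relative SSE-drop tolerance of the elbow rule.
#' @param k optional fixed k overriding the elbow choice.
#' @return a [CommunityAssignment-class].
#' @export
kmeansCommunities <- function(x, net, kRange = 2:15, nReplicates = 100,
                              seed = 1, elbowTol = 0.05, k = NULL) {
  m <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
       else as.matrix(x)
  m <- m[net@nodes, , drop = FALSE]
  feat <- t(scale(t(m)))  # per-gene z-scored profiles
  feat[!is.finite(feat)] <- 0  # constant profiles carry no shape
  nNodes <- nrow(feat)
  kRange <- sort(unique(as.integer(kRange)))
  if (!length(kRange) || any(kRange < 2L) || any(kRange > nNodes - 1L))
    stop("kRange must be non-empty and lie within [2, ", nNodes - 1L, "]")
  nDistinct <- nrow(unique(feat))
  usable <- kRange[kRange <= nDistinct]
  if (!length(usable))
    stop("fewer than 2 distinct node profiles; cannot cluster")
  if (length(usable) < length(kRange))
    message("k candidates above ", nDistinct,
            " distinct profiles dropped from the scree")
  set.seed(seed)
  fits <- lapply(usable, function(kk)
    suppressWarnings(stats::kmeans(feat, centers = kk,
                                   nstart = nReplicates, iter.max = 100L)))
  sse <- vapply(fits, function(f) f$tot.withinss, numeric(1L))
  scree <- data.frame(k = usable, sse = sse)
  if (is.null(k)) {
    k <- .elbowK(usable, sse, elbowTol)
  } else {
    k <- as.integer(k)
    if (!k %in% usable) stop("fixed k = ", k, " not among the candidates")
  }
  fit <- fits[[match(k, usable)]]
  # a larger k's best-of-replicates SSE can exceed a smaller k's optimum
  # when all restarts land in poor local minima; report the monotone
  # envelope the scree interpretation assumes
  scree$sse <- cummin(scree$sse)
  comm <- new("CommunityAssignment",
              membership = setNames(as.integer(fit$cluster), net@nodes),
              k = k, scree = scree, nReplicates = as.integer(nReplicates),
              seed = as.integer(seed))
  validObject(comm)
  comm
}

.elbowK <- function(ks, sse, tol) {
  eps <- 1e-9 * max(sse[1L], 1)
  zero <- which(sse <= eps)
  if (length(zero)) return(ks[zero[1L]])
  if (length(ks) == 1L) return(ks)
  for (i in seq_len(length(ks) - 1L)) {
    drop <- (sse[i] - sse[i + 1L]) / sse[i]
    if (drop < tol) return(ks[i])
  }
  ks[length(ks)]
}

#' Write a network as a 3-column edge TSV
#' @param net a [CorrelationNetwork-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(net, path) {
  utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
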