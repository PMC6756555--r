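# shared fixture builders; everything is generated in code

# small, fast simulation for unit tests (recovery quality not asserted here)
smallSpec <- function(seed = 1, ...) {
  syntheticSpec(nModules = 2, genesPerModule = 15, nSwitch = 4,
                nNoiseGenes = 10, nSamplesPerGroup = 10, seed = seed, ...)
}

# experiment from an explicit matrix; first half of samples control
makeSe <- function(values, nControl = ncol(values) / 2) {
  groups <- rep(c("control", "disease"),
                c(nControl, ncol(values) - nControl))
  switchExperiment(values, setNames(groups, colnames(values)))
}

namedMatrix <- function(values, nrow, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- if (is.null(genes)) paste0("g", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m)))
                 else samples
  m
}

# hand-buildable network/community objects for formula-level tests
makeNet <- function(edges, rThreshold = 0.2, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  new("CorrelationNetwork", nodes = nodes, edges = edges,
      rThreshold = rThreshold)
}

makeComm <- function(membership, k = max(membership)) {
  new("CommunityAssignment",
      membership = setNames(as.integer(membership), names(membership)),
      k = as.integer(k),
      scree = data.frame(k = k, sse = 0), nReplicates = 1L, seed = 1L)
}

# independent oracles -------------------------------------------------------

# textbook Pearson r as an explicit loop-free closed form
bruteR <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# literal step-up definition of the BH adjustment
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) n * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# betweenness by enumeration: Floyd-Warshall distances, then for every
# unordered pair (s, t) count, for each interior v, the fraction of shortest
# s-t paths through v (path counts by DP over distance layers)
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  npaths <- function(s, t) {
    if (s == t) return(1)
    sum(vapply(which(adj[, t] > 0 & d[s, ] == d[s, t] - 1),
               function(w) npaths(s, w), numeric(1)))
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    tot <- npaths(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (d[s, v] + d[v, t] == d[s, t])
        btw[v] <- btw[v] + npaths(s, v) * npaths(v, t) / tot
    }
  }
  btw
}
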