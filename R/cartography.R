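#' Heat-cartography coordinates per network node
#'
#' For node i with total degree k_i, of which kappa_i edges stay inside its
#' own community:
#' \itemize{
#'   \item `zg` — within-module degree z-score:
#'     `(kappa_i - mean(kappa_j)) / sd(kappa_j)` over the nodes j of i's
#'     community, with the population sd; 0 when the sd is 0.
#'   \item `kpi` — clusterphobic coefficient `1 - (kappa_i / k_i)^2`:
#'     0 when all links are internal, approaching 1 as the external fraction
#'     grows.
#'   \item `apcc` — average (signed) Pearson correlation between the node's
#'     expression profile and those of its network neighbours, i.e. the mean
#'     weight of its incident edges.
#' }
#'
#' @param net a [CorrelationNetwork-class].
#' @param comm a [CommunityAssignment-class] covering all network nodes.
#' @param x unused placeholder kept for interface symmetry; the incident
#'   edge weights already carry the correlations. Defaults to `NULL`.
#' @return data.frame with columns `gene`, `community`, `degree`, `zg`,
#'   `kpi`, `apcc`.
#' @export
computeCartography <- function(net, comm, x = NULL) {
  mem <- comm@membership
  if (!all(net@nodes %in% names(mem)))
    stop("every network node needs a community")
  mem <- mem[net@nodes]
  ed <- net@edges
  ids <- net@nodes
  deg <- setNames(integer(length(ids)), ids)
  kappa <- setNames(integer(length(ids)), ids)
  apccSum <- setNames(numeric(length(ids)), ids)
  tabA <- table(factor(ed$node_a, levels = ids))
  tabB <- table(factor(ed$node_b, levels = ids))
  deg[] <- as.integer(tabA + tabB)
  internal <- mem[ed$node_a] == mem[ed$node_b]
  tabAi <- table(factor(ed$node_a[internal], levels = ids))
  tabBi <- table(factor(ed$node_b[internal], levels = ids))
  kappa[] <- as.integer(tabAi + tabBi)
  sumA <- tapply(ed$r, factor(ed$node_a, levels = ids), sum, default = 0)
  sumB <- tapply(ed$r, factor(ed$node_b, levels = ids), sum, default = 0)
  apccSum[] <- sumA + sumB
  if (any(deg == 0))
    stop("every node needs at least one neighbour")

  zg <- numeric(length(ids))
  for (cidx in unique(mem)) {
    inC <- mem == cidx
    kc <- kappa[inC]
    mu <- mean(kc)
    sdPop <- sqrt(mean((kc - mu)^2))
    zg[inC] <- if (sdPop > 0) (kc - mu) / sdPop else 0
  }
  data.frame(gene = ids, community = as.integer(mem), degree = as.integer(deg),
             zg = zg, kpi = 1 - (kappa / deg)^2, apcc = apccSum / deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify nodes into roles, hub taxonomy and switch genes
#'
#' Adds to the cartography table:
#' \itemize{
#'   \item `region` — the (kpi, zg) plane partitioned at `zg = zgSwitchMax`
#'     and kpi breakpoints 0.3 / 0.6 / 0.8: non-hub rows R1-R4 (R4 is
#'     `kpi > 0.8`), local-hub rows R5-R7. Presentation-only except R4.
#'   \item `hub_class` — by the sign/magnitude of the average co-expression
#'     with partners: `fight-club` when `apcc < 0`, `party` when
#'     `apcc >= partyApccMin` (default 0.5), `date` otherwise.
#'   \item `is_hub` — local hub flag, `zg > zgHub` (default 5).
#'   \item `is_switch` — `zg < 2.5 & kpi > 0.8 & apcc < 0`: non-hubs of
#'     their own cluster, connected mainly outside it, anti-correlated with
#'     their interaction partners. Switch nodes lie in region R4.
#' }
#'
#' @param cart result of [computeCartography()].
#' @param zgSwitchMax Zg upper bound of the switch criterion (default 2.5).
#' @param kpiSwitchMin Kpi lower bound of the switch criterion (default 0.8).
#' @param zgHub Zg above which a node is a local hub (default 5).
#' @param partyApccMin APCC boundary between date and party hubs
#'   (default 0.5).
#' @return `cart` with columns `region`, `hub_class`, `is_hub`, `is_switch`
#'   appended.
#' @export
classifyNodes <- function(cart, zgSwitchMax = 2.5, kpiSwitchMin = 0.8,
                          zgHub = 5, partyApccMin = 0.5) {
  stopifnot(all(c("zg", "kpi", "apcc") %in% colnames(cart)))
  kpiBand <- findInterval(cart$kpi, c(0.3, 0.6, 0.8), left.open = TRUE)
  cart$region <- ifelse(cart$zg < zgSwitchMax,
                        paste0("R", 1L + kpiBand),
                        paste0("R", 5L + pmin(kpiBand, 2L)))
  cart$hub_class <- ifelse(cart$apcc < 0, "fight-club",
                           ifelse(cart$apcc >= partyApccMin, "party", "date"))
  cart$hub_class[is.na(cart$apcc)] <- "none"
  cart$is_hub <- cart$zg > zgHub
  cart$is_switch <- cart$zg < zgSwitchMax & cart$kpi > kpiSwitchMin &
    cart$apcc < 0
  cart
}

#' Write a cartography table as TSV
#' @param cart classified cartography table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCartography <- function(cart, path) {
  utils::write.table(cart, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
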