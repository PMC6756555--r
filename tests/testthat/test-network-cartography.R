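test_that("matrix Pearson r matches the textbook closed form to 1e-12", {
  set.seed(31)
  m <- namedMatrix(rnorm(8 * 12), nrow = 8)
  cc <- cor(t(m))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(cc[i, j], bruteR(m[i, ], m[j, ]), tolerance = 1e-12)
})

test_that("edges keep signed weights; correlated and anti-correlated pairs", {
  x <- c(1, 3, 2, 5, 4, 6)
  m <- namedMatrix(c(x, x, 2 * mean(x) - x), nrow = 3,
                   genes = c("a", "b", "c"))
  net <- buildCorrelationNetwork(m + matrix(rnorm(18, sd = 1e-9), 3),
                                 rThreshold = 0.9)
  ed <- edges(net)
  ab <- ed$r[(ed$node_a == "a" & ed$node_b == "b") |
               (ed$node_a == "b" & ed$node_b == "a")]
  ac <- ed$r[(ed$node_a == "a" & ed$node_b == "c") |
               (ed$node_a == "c" & ed$node_b == "a")]
  expect_equal(ab, 1, tolerance = 1e-6)
  expect_equal(ac, -1, tolerance = 1e-6)   # anti-correlation kept, signed
})

test_that("nodes below threshold become isolated and are dropped", {
  set.seed(32)
  base <- rnorm(20)
  m <- rbind(g1 = base + rnorm(20, sd = 0.01),
             g2 = base + rnorm(20, sd = 0.01),
             g3 = rnorm(20))
  colnames(m) <- paste0("s", 1:20)
  # brute-force oracle: exactly the g1-g2 pair exceeds the threshold
  rs <- c(bruteR(m[1, ], m[2, ]), bruteR(m[1, ], m[3, ]),
          bruteR(m[2, ], m[3, ]))
  expect_true(rs[1] > 0.95 && all(abs(rs[2:3]) < 0.95))
  expect_message(net <- buildCorrelationNetwork(m, rThreshold = 0.95),
                 "isolated")
  expect_setequal(nodes(net), c("g1", "g2"))
  expect_equal(nrow(edges(net)), 1)
})

test_that("zero-variance genes are excluded with a warning", {
  set.seed(33)
  m <- namedMatrix(c(rnorm(20), rep(5, 10)), nrow = 3)
  m[2, ] <- m[1, ] + rnorm(10, sd = 0.01)
  expect_warning(net <- buildCorrelationNetwork(m, rThreshold = 0.5),
                 "zero-variance")
  expect_false("g3" %in% nodes(net))
  expect_error(
    suppressWarnings(buildCorrelationNetwork(m, rThreshold = 0.999999)),
    "lower threshold")
})

test_that("k-means separates well-separated profile clouds exactly", {
  # clustering works on z-scored profiles, so the clouds differ in profile
  # shape: three orthogonal sample patterns plus small noise
  set.seed(34)
  patterns <- rbind(rep(c(3, -3), each = 20),
                    rep(c(3, -3), times = 20),
                    rep(rep(c(3, -3), each = 4), times = 5))
  m <- patterns[rep(1:3, each = 20), ] + rnorm(60 * 40, sd = 0.1)
  rownames(m) <- paste0("g", 1:60); colnames(m) <- paste0("s", 1:40)
  planted <- rep(1:3, each = 20)
  net <- buildCorrelationNetwork(m, rThreshold = 0.5)
  comm <- kmeansCommunities(m, net, kRange = 2:8, nReplicates = 20,
                            seed = 1)
  expect_equal(chosenK(comm), 3L)
  tab <- table(planted, communityMembership(comm)[rownames(m)])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("SSE hits zero when k equals the number of distinct profiles", {
  # 12 genes but only 3 distinct (non-constant) sample profiles
  patterns <- rbind(c(1, 2, 3, 4, 5, 6),
                    c(6, 5, 4, 3, 2, 1),
                    c(1, 6, 1, 6, 1, 6))
  m <- patterns[rep(1:3, each = 4), ]
  rownames(m) <- paste0("g", 1:12); colnames(m) <- paste0("s", 1:6)
  net <- makeNet(data.frame(node_a = rownames(m)[1:11],
                            node_b = rownames(m)[2:12],
                            r = 0.9), nodes = rownames(m))
  expect_message(
    comm <- kmeansCommunities(m, net, kRange = 2:10, nReplicates = 5,
                              seed = 2),
    "distinct")
  scree <- screeTable(comm)
  expect_equal(min(scree$sse), 0, tolerance = 1e-9)
  expect_equal(chosenK(comm), 3L)
})

test_that("best-of-replicates SSE is non-increasing in k", {
  set.seed(35)
  for (rep in seq_len(20)) {
    m <- matrix(rnorm(30 * 10), nrow = 30,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    net <- makeNet(data.frame(node_a = paste0("g", 1:29),
                              node_b = paste0("g", 2:30), r = 0.9),
                   nodes = paste0("g", 1:30))
    comm <- kmeansCommunities(m, net, kRange = 2:8, nReplicates = 10,
                              seed = rep)
    expect_true(all(diff(screeTable(comm)$sse) <= 1e-8))
  }
})

test_that("k-means assignment is deterministic given the seed", {
  sim <- generateDataset(smallSpec(seed = 36))
  m <- SummarizedExperiment::assay(sim$experiment)
  net <- buildCorrelationNetwork(m, rThreshold = 0.5)
  c1 <- kmeansCommunities(m, net, kRange = 2:6, nReplicates = 10, seed = 9)
  c2 <- kmeansCommunities(m, net, kRange = 2:6, nReplicates = 10, seed = 9)
  expect_identical(communityMembership(c1), communityMembership(c2))
  expect_error(kmeansCommunities(m, net, kRange = integer()), "kRange")
  expect_error(kmeansCommunities(m, net, kRange = 1:2), "kRange")
})

test_that("hand-computed cartography: zg (sqrt 2 case), kpi limits, apcc", {
  # community 1 = {a, b, c} with internal edges a-b, a-c: within-degrees
  # (2, 1, 1); community 2 = {d, e} with edge d-e; a-d crosses communities
  ed <- data.frame(node_a = c("a", "a", "d", "a"),
                   node_b = c("b", "c", "e", "d"),
                   r = c(1, 1, 1, -0.4))
  net <- makeNet(ed, rThreshold = 0.2)
  comm <- makeComm(c(a = 1, b = 1, c = 1, d = 2, e = 2))
  cart <- computeCartography(net, comm)
  rownames(cart) <- cart$gene
  expect_equal(cart[c("a", "b", "c"), "zg"],
               c(sqrt(2), -sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-12)
  # b: all links internal -> kpi = 0; a: 2 of 3 internal -> 1 - (2/3)^2
  expect_equal(cart["b", "kpi"], 0, tolerance = 1e-12)
  expect_equal(cart["a", "kpi"], 1 - (2 / 3)^2, tolerance = 1e-12)
  # d: one internal of two links -> kpi = 1 - (1/2)^2 = 0.75
  expect_equal(cart["d", "kpi"], 0.75, tolerance = 1e-12)
  # apcc averages signed incident weights: a -> (1 + 1 - 0.4)/3
  expect_equal(cart["a", "apcc"], (1 + 1 - 0.4) / 3, tolerance = 1e-12)
  expect_equal(cart["d", "apcc"], (1 - 0.4) / 2, tolerance = 1e-12)
})

test_that("a node with only external links reaches kpi = 1", {
  ed <- data.frame(node_a = c("x", "x", "y"),
                   node_b = c("y", "z", "z"), r = c(0.9, 0.9, 0.9))
  net <- makeNet(ed)
  comm <- makeComm(c(x = 1, y = 2, z = 2))
  cart <- computeCartography(net, comm)
  expect_equal(cart$kpi[cart$gene == "x"], 1)
  # single neighbour at r = -0.4 -> apcc = -0.4
  ed2 <- data.frame(node_a = c("x", "y"), node_b = c("y", "z"),
                    r = c(-0.4, 0.9))
  cart2 <- computeCartography(makeNet(ed2), makeComm(c(x = 1, y = 1, z = 1)))
  expect_equal(cart2$apcc[cart2$gene == "x"], -0.4)
})

test_that("zg is standardized within every community; ranges hold", {
  sim <- generateDataset(smallSpec(seed = 37))
  m <- SummarizedExperiment::assay(sim$experiment)
  net <- buildCorrelationNetwork(m, rThreshold = 0.6)
  comm <- kmeansCommunities(m, net, kRange = 2:6, nReplicates = 20,
                            seed = 3)
  cart <- computeCartography(net, comm)
  for (cl in unique(cart$community)) {
    z <- cart$zg[cart$community == cl]
    if (any(z != 0)) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
    }
  }
  expect_true(all(cart$kpi >= 0 & cart$kpi <= 1))
  expect_true(all(cart$apcc >= -1 & cart$apcc <= 1))
})

test_that("switch criteria classify the boundary nodes exactly", {
  cart <- data.frame(gene = c("n1", "n2", "n3"),
                     community = 1L, degree = 10L,
                     zg = c(2.4, 2.4, 6.0),
                     kpi = c(0.85, 0.85, 0.9),
                     apcc = c(-0.1, 0.1, -0.2))
  out <- classifyNodes(cart)
  expect_identical(out$is_switch, c(TRUE, FALSE, FALSE))
  expect_identical(out$hub_class, c("fight-club", "date", "fight-club"))
  expect_identical(out$region, c("R4", "R4", "R7"))
  expect_true(out$is_hub[3])
  # switch nodes always fall in region R4
  expect_true(all(out$region[out$is_switch] == "R4"))
})

test_that("switch calls are invariant to node order and label permutation", {
  sim <- generateDataset(smallSpec(seed = 38))
  m <- SummarizedExperiment::assay(sim$experiment)
  net <- buildCorrelationNetwork(m, rThreshold = 0.6)
  comm <- kmeansCommunities(m, net, kRange = 2:6, nReplicates = 20,
                            seed = 4)
  cart1 <- classifyNodes(computeCartography(net, comm))
  sw1 <- sort(cart1$gene[cart1$is_switch])

  # shuffled gene order, same fixed threshold -> same network, same calls
  set.seed(39)
  m2 <- m[sample(nrow(m)), ]
  net2 <- buildCorrelationNetwork(m2, rThreshold = 0.6)
  cart2 <- classifyNodes(computeCartography(net2, comm))
  expect_identical(sort(cart2$gene[cart2$is_switch]), sw1)

  # relabelled community indices -> identical switch set
  mem <- communityMembership(comm)
  relabel <- rev(seq_len(chosenK(comm)))
  comm3 <- makeComm(setNames(relabel[mem], names(mem)))
  cart3 <- classifyNodes(computeCartography(net, comm3))
  expect_identical(sort(cart3$gene[cart3$is_switch]), sw1)
})
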