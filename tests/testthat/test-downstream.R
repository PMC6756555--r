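test_that("hypergeometric tail and fold enrichment match exact values", {
  universe <- paste0("g", 1:20)
  gsc <- geneSetCollection(list(S = paste0("g", 1:5)), universe)
  # query of 5 hitting all 5 set members: p = 1 / C(20, 5)
  res <- hypergeometricEnrichment(paste0("g", 1:5), gsc)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (5 / 5) / (5 / 20))  # = 4
  expect_equal(res$overlap_count, 5L)
  # query = universe: overlap is forced, p = 1
  resAll <- hypergeometricEnrichment(universe, gsc)
  expect_equal(resAll$p_value, 1)
  # EASE variant subtracts one from the overlap
  resEase <- hypergeometricEnrichment(paste0("g", 1:5), gsc, ease = TRUE)
  expect_equal(resEase$p_value,
               phyper(3, 5, 15, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(resEase$p_value, res$p_value)
})

test_that("hypergeometric p agrees with Monte-Carlo resampling", {
  set.seed(51)
  universe <- paste0("g", 1:30)
  s <- paste0("g", 1:8)
  query <- paste0("g", c(1:4, 20:25))  # overlap 4, query size 10
  gsc <- geneSetCollection(list(S = s), universe)
  p <- hypergeometricEnrichment(query, gsc)$p_value
  draws <- replicate(1e5, sum(sample.int(30, 10) <= 8) >= 4)
  mc <- mean(draws)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(p - mc), 3 * se)
})

test_that("query genes outside the universe are dropped with a warning", {
  gsc <- geneSetCollection(list(S = c("a", "b")), c("a", "b", "c"))
  expect_warning(res <- hypergeometricEnrichment(c("a", "zzz"), gsc),
                 "outside the universe")
  expect_equal(res$query_size, 1L)
  expect_error(
    suppressWarnings(hypergeometricEnrichment("zzz", gsc)), "empty")
  expect_error(geneSetCollection(list(S = character()), "a"), "empty")
  expect_error(geneSetCollection(list(S = "zzz"), c("a", "b")), "disjoint")
})

test_that("GMT collections read through the standard parser", {
  gmt <- readGmt(system.file("extdata", "synthetic_gene_sets.gmt",
                             package = "switchcart"))
  expect_named(gmt, c("PATH_A", "PATH_B", "PATH_C"))
  expect_true("SW_1" %in% gmt$PATH_A && "SW_1" %in% gmt$PATH_B)
  expect_length(gmt$PATH_C, 3L)
})

test_that("overlap counts give UpSet-exclusive and Venn-pairwise semantics", {
  sets <- list(A = c("x", "y", "z"), B = c("x", "y", "z"))
  oc <- overlapCounts(sets)
  expect_equal(oc$pairwise["A", "B"], 3L)
  excl <- setNames(oc$exclusive$count, oc$exclusive$combination)
  expect_equal(unname(excl["A&B"]), 3L)
  expect_equal(unname(excl["A"] + excl["B"]), 0L)

  disjoint <- overlapCounts(list(A = c("x", "y"), B = c("p", "q")))
  expect_equal(disjoint$pairwise["A", "B"], 0L)
  exclD <- setNames(disjoint$exclusive$count, disjoint$exclusive$combination)
  expect_equal(unname(exclD["A&B"]), 0L)

  # three-set case: exclusive counts partition the union
  set.seed(52)
  sets3 <- list(A = sample(letters, 12), B = sample(letters, 8),
                C = sample(letters, 15))
  oc3 <- overlapCounts(sets3)
  expect_equal(sum(oc3$exclusive$count),
               length(unique(unlist(sets3))))
  expect_equal(nrow(oc3$exclusive), 2^3 - 1)
  expect_equal(unname(diag(oc3$pairwise)), lengths(sets3, use.names = FALSE))
})

test_that("TF edge filtering applies both strict bounds and deduplicates", {
  edges <- readTfEdges(system.file("extdata", "synthetic_tf_edges.tsv",
                                   package = "switchcart"))
  out <- filterTfEdges(edges)
  # peak 600 out; regulatory potential exactly 1 out (strict); 499.9/0.99 in
  expect_false(any(out$tf == "TF2" & out$target == "SW_2"))
  expect_false(any(out$tf == "TF3" & out$target == "SW_3"))
  expect_true(any(out$tf == "TF2" & out$target == "SW_1"))
  expect_true(all(out$peak_intensity < 500 & out$regulatory_potential < 1))
  # subset of input, idempotent
  expect_true(nrow(out) <= nrow(edges))
  expect_identical(filterTfEdges(out), out)
  # duplicates collapse
  dup <- rbind(out, out)
  expect_identical(filterTfEdges(dup), out)
  expect_error(filterTfEdges(out[, 1:2]), "missing column")
})

test_that("TF ranking follows degree, then betweenness, then symbol", {
  # TFa targets every query gene; TFb and TFc one each
  edges <- data.frame(tf = c("TFa", "TFa", "TFa", "TFb", "TFc"),
                      target = c("q1", "q2", "q3", "q1", "q2"),
                      peak_intensity = 1, regulatory_potential = 0.1)
  rk <- rankTfs(edges, c("q1", "q2", "q3"))
  expect_identical(rk$tf[1], "TFa")
  expect_equal(rk$degree[1], 3L)
  expect_true(rk$betweenness[1] >= max(rk$betweenness[-1]))
  expect_identical(rk$rank, 1:3)
  # pure tie on degree and betweenness -> lexicographic symbols
  tie <- data.frame(tf = c("Z", "A"), target = c("q1", "q2"),
                    peak_intensity = 1, regulatory_potential = 0.1)
  expect_identical(rankTfs(tie, c("q1", "q2"))$tf, c("A", "Z"))
  expect_warning(empty <- rankTfs(tie, "unrelated"), "empty ranking")
  expect_equal(nrow(empty), 0L)
})

test_that("betweenness matches brute-force path enumeration", {
  # bipartite chain TF1 - q1 - TF2 - q2 - TF3: a 5-node path
  edges <- data.frame(tf = c("TF1", "TF2", "TF2", "TF3"),
                      target = c("q1", "q1", "q2", "q2"),
                      peak_intensity = 1, regulatory_potential = 0.1)
  rk <- rankTfs(edges, c("q1", "q2"))
  # adjacency of the path TF1-q1-TF2-q2-TF3
  adj <- matrix(0, 5, 5,
                dimnames = list(c("TF1", "q1", "TF2", "q2", "TF3"), NULL))
  adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- adj[4, 5] <- 1
  adj <- adj + t(adj)
  ref <- bruteBetweenness(adj)  # (0, 3, 4, 3, 0)
  expect_equal(ref, c(0, 3, 4, 3, 0))
  expect_equal(rk$betweenness[rk$tf == "TF2"], ref[3])
  expect_equal(rk$betweenness[rk$tf == "TF1"], 0)
  expect_equal(rk$betweenness[rk$tf == "TF3"], 0)
})
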