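test_that("modularity identities hold on simple partitions", {
  W <- adjacencyOf(barbellNetwork())
  n <- nrow(W)
  # single community: Q = 0
  expect_equal(graphModularity(W, rep(1, n)), 0)
  # all singletons, no self-loops: Q = -sum (s_v / 2W)^2 < 0
  sv <- rowSums(W); tw <- sum(W) / 2
  expect_equal(graphModularity(W, seq_len(n)),
               0 - sum((sv / (2 * tw))^2))
  expect_lt(graphModularity(W, seq_len(n)), 0)
  # the two-triangle partition of the barbell: Q = 5/14
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(graphModularity(barbellNetwork(), memb), 5 / 14)
})

test_that("modularity agrees with igraph on random weighted graphs", {
  for (seed in 1:10) {
    net <- randomNetwork(12, p = 0.35, seed = seed)
    g <- asIgraph(net)
    n <- nrow(networkNodes(net))   # isolated vertices are not materialized
    memb <- sample(1:3, n, replace = TRUE)
    names(memb) <- networkNodes(net)$name
    expect_equal(graphModularity(net, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("membership validation catches unknown and missing nodes", {
  net <- barbellNetwork()
  bad <- c(a = 1, b = 1, c = 1, d = 2, e = 2, z = 2)
  expect_error(graphModularity(net, bad), "missing node")
  expect_error(graphModularity(net, c(a = 1)), "missing node")
})

test_that("the two-triangle barbell splits into its triangles at Q = 5/14", {
  cp <- walktrapCommunities(barbellNetwork(), steps = 4)
  memb <- communityMembership(cp)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb[c("d", "e", "f")])), 1)
  expect_false(memb[["a"]] == memb[["d"]])
  expect_equal(max(modularityTrace(cp)), 5 / 14, tolerance = 1e-12)
})

test_that("disconnected cliques are separated exactly and never merged", {
  net <- cliquesNetwork(4, 5)
  cp <- walktrapCommunities(net)
  memb <- communityMembership(cp)
  expect_equal(length(unique(memb)), 2)
  expect_equal(unname(memb[paste0("x", 1:4)]), rep(memb[["x1"]], 4))
  expect_equal(unname(memb[paste0("y", 1:5)]), rep(memb[["y1"]], 5))
  # merge count = n - #components
  expect_equal(nrow(mergeOrder(cp)), 9 - 2)
})

test_that("walktrap matches the igraph reference on clean fixtures", {
  for (net in list(barbellNetwork(), cliquesNetwork(5, 5),
                   k10PendantNetwork())) {
    g <- asIgraph(net)
    ref <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                    steps = 4)
    memb <- communityMembership(walktrapCommunities(net, steps = 4))
    refMemb <- igraph::membership(ref)[names(memb)]
    expect_equal(mclust::adjustedRandIndex(memb, refMemb), 1)
  }
})

test_that("best-cut modularity dominates every dendrogram cut", {
  for (seed in c(2, 5, 9)) {
    net <- randomNetwork(10, p = 0.4, seed = seed)
    cp <- walktrapCommunities(net)
    qBest <- max(modularityTrace(cp))
    for (k in 0:nrow(mergeOrder(cp))) {
      memb <- cutPartition(cp, k)
      q <- graphModularity(net, memb)
      expect_equal(q, modularityTrace(cp)[k + 1], tolerance = 1e-12)
      expect_lte(q, qBest + 1e-12)
    }
  }
})

test_that("best cut attains the brute-force maximum on the fixtures", {
  # enumerate all partitions of the 6-node barbell (Bell(6) = 203)
  allPartitions <- function(n) {
    out <- list(1L)
    for (i in 2:n) {
      nxt <- list()
      for (p in out) {
        k <- max(p)
        for (c in seq_len(k + 1)) nxt[[length(nxt) + 1]] <- c(p, c)
      }
      out <- nxt
    }
    out
  }
  net <- barbellNetwork()
  best <- max(vapply(allPartitions(6),
                     function(p) graphModularity(net, p), 0))
  cp <- walktrapCommunities(net)
  expect_equal(max(modularityTrace(cp)), best, tolerance = 1e-12)
})

test_that("isolated nodes stay singleton and the walk remains defined", {
  net <- mkNetwork(from = c("a", "b"), to = c("b", "c"),
                   nodes = c("a", "b", "c", "lonely"))
  cp <- walktrapCommunities(net)
  memb <- communityMembership(cp)
  expect_equal(sum(memb == memb[["lonely"]]), 1)
  expect_equal(nrow(mergeOrder(cp)), 4 - 2)
})

test_that("negative weights are rejected with advice to use |rho|", {
  W <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  expect_error(walktrapCommunities(W), "rho")
})

test_that("planted two-block data are recovered through the full pipeline", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulateDataset(testConfig(seed = 100 + seed))
    prep <- prepareAnalysisMatrix(sim$abundance, traits = NULL,
                                  state = "dehydrated")
    cs <- correlationMatrix(prep$matrix)
    net <- buildNetwork(cs, rThresh = 0.5, qTarget = 0.05)
    memb <- communityMembership(walktrapCommunities(net))
    ari <- mclust::adjustedRandIndex(memb, sim$truth$blockAssignment[names(memb)])
    if (ari >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
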