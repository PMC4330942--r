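test_that("the exact signed-rank null handles fully tied differences", {
  # ten equal positive differences: V is maximal, two-sided p = 2/2^10
  res <- wilcoxonSignedRank(rep(8, 10))
  expect_true(res$exact)
  expect_equal(res$statistic, 55)
  expect_equal(res$pValue, 2 / 1024)
})

test_that("exact p-values match wilcox.test on tie-free differences", {
  set.seed(30)
  for (i in 1:30) {
    n <- sample(5:15, 1)
    d <- rnorm(n)
    ref <- wilcox.test(d, exact = TRUE)
    got <- wilcoxonSignedRank(d)
    expect_true(got$exact)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$pValue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("one-sided alternatives integrate the matching tail", {
  d <- c(3, 5, 7, 9, 11)
  g <- wilcoxonSignedRank(d, alternative = "greater")
  l <- wilcoxonSignedRank(d, alternative = "less")
  expect_equal(g$pValue, 1 / 32)    # all-positive, maximal V
  expect_equal(l$pValue, 1)
  ref <- wilcox.test(d, alternative = "greater", exact = TRUE)
  expect_equal(g$pValue, ref$p.value, tolerance = 1e-12)
})

test_that("all-zero differences are degenerate with p = 1", {
  res <- wilcoxonSignedRank(rep(0, 12))
  expect_true(res$degenerate)
  expect_equal(res$pValue, 1)
  expect_equal(res$nZeroDropped, 12)
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(31)
  d <- rnorm(60, mean = 0.4)
  got <- wilcoxonSignedRank(d)
  expect_false(got$exact)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$pValue, ref$p.value, tolerance = 1e-10)
})

test_that("K10 with one pendant edge per node gives exact p = 2/1024", {
  net <- k10PendantNetwork()
  memb <- setNames(ifelse(grepl("^c", networkNodes(net)$name), 1, 2),
                   networkNodes(net)$name)
  deg <- communityDegrees(net, memb, 1)
  expect_equal(deg$internal, rep(9, 10))
  expect_equal(deg$residual, rep(1, 10))
  res <- communitySignificance(net, memb, minSize = 9)
  row1 <- res[res$community == 1, ]
  expect_true(row1$tested)
  expect_equal(row1$pValue, 2 / 1024)
})

test_that("communities of nine or fewer nodes are not tested", {
  net <- cliquesNetwork(9, 10)
  memb <- setNames(ifelse(grepl("^x", networkNodes(net)$name), 1, 2),
                   networkNodes(net)$name)
  res <- communitySignificance(net, memb, minSize = 9)
  expect_false(res$tested[res$community == 1])   # size 9: excluded
  expect_true(res$tested[res$community == 2])    # size 10: tested
  expect_true(is.na(res$pValue[res$community == 1]))
})

test_that("internal plus residual degree equals the full-network degree", {
  for (seed in 1:20) {
    net <- randomNetwork(n = sample(8:25, 1), p = runif(1, 0.15, 0.5),
                         seed = 40 + seed)
    n <- nrow(networkNodes(net))
    memb <- setNames(sample(1:3, n, replace = TRUE),
                     networkNodes(net)$name)
    full <- nodeDegree(net)
    for (c0 in unique(memb)) {
      deg <- communityDegrees(net, memb, c0)
      expect_equal(deg$internal + deg$residual,
                   unname(full[deg$node]))
    }
  }
})

test_that("a community as connected outside as inside is degenerate", {
  # 12-clique where each member also has 11 external pendant neighbors:
  # internal degree = residual degree = 11 for every node
  core <- sprintf("c%02d", 1:12)
  ek <- t(combn(core, 2))
  pendFrom <- rep(core, each = 11)
  pendTo <- sprintf("q%03d", seq_len(12 * 11))
  net <- mkNetwork(from = c(ek[, 1], pendFrom), to = c(ek[, 2], pendTo))
  memb <- setNames(ifelse(grepl("^c", networkNodes(net)$name), 1, 2),
                   networkNodes(net)$name)
  res <- communitySignificance(net, memb, minSize = 9)
  row1 <- res[res$community == 1, ]
  expect_true(row1$degenerate)
  expect_equal(row1$pValue, 1)
})

test_that("significance p-values are roughly uniform under rewiring", {
  # degree-preserving rewires of a random graph destroy any community
  # structure; with the candidate community covering half the node pairs
  # (21 of 41 nodes: 20 internal vs 20 external partners per member) the
  # internal/residual comparison is balanced under the null, so its
  # p-values should look uniform
  set.seed(33)
  g0 <- igraph::sample_gnp(41, 0.3)
  nodes <- as.character(1:41)
  memb <- setNames(c(rep(1, 21), rep(2, 20)), nodes)
  ps <- replicate(200, {
    g <- igraph::rewire(g0, igraph::keeping_degseq(niter = 500))
    ed <- igraph::as_edgelist(g)
    net <- mkNetwork(from = as.character(ed[, 1]),
                     to = as.character(ed[, 2]), nodes = nodes)
    res <- communitySignificance(net, memb, minSize = 9)
    res$pValue[res$community == 1]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.15)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
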