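test_that("edges require both |rho| above and p below their thresholds", {
  rho <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  rho["A", "B"] <- rho["B", "A"] <- 0.9
  rho["A", "C"] <- rho["C", "A"] <- 0.4
  rho["B", "C"] <- rho["C", "B"] <- -0.8
  pv <- matrix(1e-6, 3, 3)
  cs <- statsFromMatrices(rho, pv)
  net <- buildNetwork(cs, rThresh = 0.5, pThresh = 0.05)
  ed <- networkEdges(net)
  expect_setequal(paste(ed$from, ed$to), c("A B", "B C"))
  expect_equal(ed$sign[ed$from == "A"], 1)
  expect_equal(ed$sign[ed$to == "C"], -1)
  expect_equal(nrow(networkNodes(net)), 3)   # isolated C retained
})

test_that("boundary thresholds give the empty and the complete graph", {
  set.seed(20)
  cs <- correlationMatrix(matrix(rnorm(72), 12, 6))
  expect_equal(nrow(networkEdges(buildNetwork(cs, rThresh = 1,
                                              pThresh = 1))), 0)
  full <- buildNetwork(cs, rThresh = 0, pThresh = 1)
  expect_equal(nrow(networkEdges(full)), choose(6, 2))
})

test_that("raising r or lowering p never adds an edge", {
  set.seed(21)
  cs <- correlationMatrix(matrix(rnorm(12 * 10), 12, 10))
  edgeKey <- function(net) {
    ed <- networkEdges(net)
    paste(ed$from, ed$to)
  }
  rs <- c(0.2, 0.4, 0.6, 0.8)
  for (i in seq_len(length(rs) - 1)) {
    eLo <- edgeKey(buildNetwork(cs, rThresh = rs[i], pThresh = 0.5))
    eHi <- edgeKey(buildNetwork(cs, rThresh = rs[i + 1], pThresh = 0.5))
    expect_true(all(eHi %in% eLo))
  }
  ps <- c(0.5, 0.1, 0.01)
  for (i in seq_len(length(ps) - 1)) {
    eLo <- edgeKey(buildNetwork(cs, rThresh = 0.3, pThresh = ps[i]))
    eHi <- edgeKey(buildNetwork(cs, rThresh = 0.3, pThresh = ps[i + 1]))
    expect_true(all(eHi %in% eLo))
  }
})

test_that("network properties match closed forms on K4 and P4", {
  k4 <- cliquesNetwork(4, 2)
  k4 <- induceSubnetwork(k4, paste0("x", 1:4))
  pk <- networkProperties(k4)
  expect_equal(pk$avgDegree, 3)
  expect_equal(pk$density, 1)
  expect_equal(pk$clustering, 1)
  expect_equal(pk$diameter, 1)
  p4 <- mkNetwork(from = c("a", "b", "c"), to = c("b", "c", "d"))
  pp <- networkProperties(p4)
  expect_equal(pp$avgDegree, 1.5)
  expect_equal(pp$density, 0.5)
  expect_equal(pp$clustering, 0)
  expect_equal(pp$diameter, 3)
})

test_that("diameter is taken within the largest connected component", {
  twoTri <- cliquesNetwork(3, 3)
  pr <- networkProperties(twoTri)
  expect_equal(pr$diameter, 1)
  expect_equal(pr$clustering, 1)
})

test_that("properties agree with brute force on random graphs", {
  for (seed in 1:25) {
    net <- randomNetwork(n = sample(5:30, 1), p = runif(1, 0.1, 0.5),
                         seed = seed)
    got <- networkProperties(net)
    ref <- bruteProperties(adjacencyOf(net))
    expect_equal(got$avgDegree, ref$avgDegree)
    expect_equal(got$clustering, ref$clustering, tolerance = 1e-12)
    expect_equal(got$density, ref$density)
    expect_equal(got$diameter, ref$diameter)
  }
})

test_that("degenerate graphs are handled explicitly", {
  single <- mkNetwork("a", "b")
  single <- induceSubnetwork(single, "a")
  expect_warning(pr <- networkProperties(single), "density")
  expect_equal(pr$density, 0)
  expect_equal(pr$diameter, 0)
})

test_that("a two-level rho structure yields a plateau the scan finds", {
  # |rho| is either 0.2 or 0.9: once r passes 0.2 the network is
  # identical for every p below the edge p-values, so the first grid
  # point above 0.2 must be chosen
  set.seed(22)
  n <- 10
  nm <- paste0("n", 1:n)
  rho <- matrix(0.2, n, n, dimnames = list(nm, nm))
  blk <- 1:5
  rho[blk, blk] <- 0.9
  rho[6:10, 6:10] <- 0.9
  pv <- matrix(1e-8, n, n)
  cs <- statsFromMatrices(rho, pv)
  scan <- robustnessScan(cs, rGrid = seq(0.30, 0.95, 0.05),
                         pGrid = c(1e-6, 1e-5, 1e-4), stabilityTol = 0.1)
  expect_equal(scan$chosenR, 0.3)
  expect_equal(unname(scan$scores[as.character(0.3)]), 0)
})

test_that("a property curve constant across p has stability score zero", {
  rho <- matrix(0.9, 4, 4)
  pv <- matrix(1e-9, 4, 4)
  cs <- statsFromMatrices(rho, pv)
  scan <- robustnessScan(cs, rGrid = 0.5, pGrid = c(1e-6, 1e-3),
                         stabilityTol = 0.1)
  expect_equal(unname(scan$scores), 0)
})

test_that("unstable scans fall back to the score-minimizing r with a warning", {
  # on null data with a liberal p-grid the edge set keeps changing with
  # p, so no r is stable at a tight tolerance
  ab <- simulateNullDataset(simulationConfig(nMetabolites = 30,
                                             blockSizes = c(15L, 15L),
                                             blockLoadings = c(0.9, 0.9),
                                             seasonalAmplitude = c(0.3, -0.3),
                                             rngSeed = 23))
  mm <- meanNormalize(monthlyMeans(ab, state = "dehydrated"))
  cs <- correlationMatrix(paretoScale(mm))
  expect_warning(scan <- robustnessScan(cs, rGrid = c(0.3, 0.4, 0.5),
                                        pGrid = c(0.001, 0.01, 0.1, 0.5),
                                        stabilityTol = 1e-6),
                 "stability tolerance")
  expect_true(scan$chosenR %in% scan$rGrid)
})

test_that("GraphML and SIF exports are written and deterministic", {
  net <- barbellNetwork()
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, f1); writeGraphML(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  g <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::ecount(g), 7)
  expect_true("sign" %in% igraph::edge_attr_names(g))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeSIF(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 7)
  expect_true(all(grepl(" pp ", lines)))   # all-positive fixture
  expect_true(file.exists(sub("\\.sif$", "_nodes.csv", sif)))
})
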