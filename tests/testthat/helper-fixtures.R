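# Graph fixtures and independent brute-force oracles shared by the suite.

# MetaboliteNetwork from an edge list (node names inferred); unit-ish
# weights keep the validity constraints satisfied.
mkNetwork <- function(from, to, rho = 0.9, nodes = NULL, kind = NULL,
                      compoundClass = NULL) {
  rho <- rep_len(rho, length(from))
  nm <- if (is.null(nodes)) sort(unique(c(from, to))) else nodes
  if (is.null(kind)) kind <- rep("metabolite", length(nm))
  if (is.null(compoundClass)) compoundClass <- rep("other", length(nm))
  nodesDf <- data.frame(name = nm, kind = kind,
                        compoundClass = compoundClass,
                        stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, weight = abs(rho),
                      sign = sign(rho), rho = rho,
                      p = rep(1e-6, length(from)),
                      q = rep(1e-5, length(from)),
                      stringsAsFactors = FALSE)
  new("MetaboliteNetwork", nodes = nodesDf, edges = edges,
      thresholds = list(r = 0, p = 1), netMeta = list())
}

# two triangles {a,b,c} and {d,e,f} joined by the single edge c-d
barbellNetwork <- function() {
  mkNetwork(from = c("a", "a", "b", "d", "d", "e", "c"),
            to   = c("b", "c", "c", "e", "f", "f", "d"),
            rho = 1)
}

# two disjoint cliques of sizes n1, n2
cliquesNetwork <- function(n1 = 4, n2 = 5) {
  nm1 <- paste0("x", seq_len(n1)); nm2 <- paste0("y", seq_len(n2))
  e1 <- t(combn(nm1, 2)); e2 <- t(combn(nm2, 2))
  mkNetwork(from = c(e1[, 1], e2[, 1]), to = c(e1[, 2], e2[, 2]), rho = 1)
}

# K10 whose members each have exactly one pendant external edge
k10PendantNetwork <- function() {
  core <- sprintf("c%02d", 1:10)
  pend <- sprintf("p%02d", 1:10)
  ek <- t(combn(core, 2))
  mkNetwork(from = c(ek[, 1], core), to = c(ek[, 2], pend), rho = 1)
}

# Erdos-Renyi network with random weights; always at least one edge
randomNetwork <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(sprintf("v%02d", seq_len(n)), 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  mkNetwork(from = pairs[keep, 1], to = pairs[keep, 2],
            rho = runif(sum(keep), 0.2, 1) *
              sample(c(-1, 1), sum(keep), replace = TRUE))
}

adjacencyOf <- function(net) {
  nm <- networkNodes(net)$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  ed <- networkEdges(net)
  if (nrow(ed)) {
    A[cbind(ed$from, ed$to)] <- 1
    A[cbind(ed$to, ed$from)] <- 1
  }
  A
}

# brute-force network properties: triangle counting on the adjacency
# matrix and Floyd-Warshall shortest paths
bruteProperties <- function(A) {
  n <- nrow(A)
  E <- sum(A) / 2
  tri <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(rowSums(A), 2))
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) if (comp[i] == 0) {
    cid <- cid + 1
    comp[is.finite(D[i, ])] <- cid
  }
  big <- which(comp == which.max(table(comp))[[1]])
  diam <- if (E == 0) 0 else max(D[big, big][is.finite(D[big, big])])
  list(avgDegree = 2 * E / n,
       clustering = if (triples > 0) 3 * tri / triples else 0,
       density = if (n > 1) 2 * E / (n * (n - 1)) else 0,
       diameter = diam)
}

# O(m^2) brute-force BH threshold: a p-value qualifies if it is <=
# qTarget * (#p <= it) / m; return the largest qualifying p
bruteBHThreshold <- function(p, qTarget) {
  m <- length(p)
  best <- 0
  for (t in p) {
    k <- sum(p <= t)
    if (t <= qTarget * k / m && t > best) best <- t
  }
  best
}

# rank-then-Pearson Spearman oracle
rankPearson <- function(x, y) cor(rank(x), rank(y))

# CorrelationStats built directly from given rho/p matrices (diagonal
# handled here), for threshold-rule tests
statsFromMatrices <- function(rho, pval, kind = NULL, cls = NULL) {
  nv <- nrow(rho)
  nm <- rownames(rho)
  if (is.null(nm)) nm <- paste0("n", seq_len(nv))
  dimnames(rho) <- dimnames(pval) <- list(nm, nm)
  diag(rho) <- 1; diag(pval) <- 0
  qval <- matrix(NA_real_, nv, nv, dimnames = dimnames(rho))
  off <- upper.tri(qval)
  qval[off] <- p.adjust(pval[off], method = "BH")
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(qval) <- 0
  if (is.null(kind)) kind <- rep("metabolite", nv)
  if (is.null(cls)) cls <- rep("other", nv)
  new("CorrelationStats", labels = nm, rho = rho, pval = pval,
      qval = qval, nUsed = matrix(12, nv, nv), method = "spearman",
      pMethod = "exact", nodeKind = kind, compoundClass = cls)
}

# fast small simulation config for tests
testConfig <- function(seed = 1, ...) {
  simulationConfig(nMetabolites = 20, blockSizes = c(10L, 10L),
                   blockLoadings = c(0.9, 0.9),
                   seasonalAmplitude = c(0.3, -0.3),
                   rngSeed = seed, ...)
}
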