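## Random-walk (walktrap) community detection, implemented from its
## definition: communities are merged agglomeratively by the smallest
## Ward-style increase in mean squared random-walk distance, and the
## partition is read off at the modularity-maximizing cut.

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c (w_c / W - (s_c / 2W)^2)` with `w_c` the intra-community
#' edge weight, `s_c` the summed node strength of community c and `W` the
#' total edge weight. `Q = 0` for the single-community partition and is
#' negative for the all-singletons partition of any graph without
#' self-loops.
#'
#' @param net a [MetaboliteNetwork-class], igraph object, or symmetric
#'   nonnegative adjacency matrix.
#' @param membership named (or network-ordered) integer community ids
#'   covering every node.
#' @return modularity in `[-0.5, 1]`.
#' @export
graphModularity <- function(net, membership) {
  W <- .asAdjacency(net)
  n <- nrow(W)
  memb <- .alignMembership(membership, rownames(W), n)
  tw <- sum(W) / 2                      # total edge weight
  if (tw == 0) return(0)
  strength <- rowSums(W)
  q <- 0
  for (c in unique(memb)) {
    inC <- memb == c
    wc <- sum(W[inC, inC]) / 2
    sc <- sum(strength[inC])
    q <- q + wc / tw - (sc / (2 * tw))^2
  }
  q
}

.asAdjacency <- function(net) {
  if (is(net, "MetaboliteNetwork")) {
    nd <- net@nodes$name
    W <- matrix(0, length(nd), length(nd), dimnames = list(nd, nd))
    ed <- net@edges
    if (nrow(ed)) {
      W[cbind(ed$from, ed$to)] <- ed$weight
      W[cbind(ed$to, ed$from)] <- ed$weight
    }
    W
  } else if (inherits(net, "igraph")) {
    as.matrix(igraph::as_adjacency_matrix(
      net, attr = if ("weight" %in% igraph::edge_attr_names(net))
        "weight" else NULL, sparse = FALSE))
  } else {
    W <- as.matrix(net)
    if (nrow(W) != ncol(W) || any(abs(W - t(W)) > 1e-12))
      stop("adjacency matrix must be square and symmetric")
    diag(W) <- 0
    W
  }
}

.alignMembership <- function(membership, nodeNames, n) {
  if (!is.null(names(membership)) && !is.null(nodeNames)) {
    if (!all(nodeNames %in% names(membership)))
      stop("membership is missing node(s): ",
           paste(setdiff(nodeNames, names(membership)), collapse = ", "))
    extra <- setdiff(names(membership), nodeNames)
    if (length(extra))
      stop("membership names unknown node(s): ",
           paste(extra, collapse = ", "))
    membership <- membership[nodeNames]
  }
  if (length(membership) != n)
    stop("membership must assign every node to exactly one community")
  as.integer(factor(membership))
}

#' Walktrap community detection
#'
#' Implements Pons-Latapy random-walk community detection on the signed
#' correlation network (edge weights are |rho|; negative weights are
#' rejected). Node distances are
#' \deqn{r_{ij}^2 = \sum_k (P^t_{ik} - P^t_{jk})^2 / d(k)}
#' with `P` the row-normalized weighted adjacency matrix and `d` the node
#' strengths (isolated nodes receive a unit self-loop so the walk is
#' defined). Starting from singletons, the two *adjacent* communities
#' whose merge minimizes the Ward-style increase in mean squared distance
#' \deqn{\Delta\sigma(C_1, C_2) = \frac{1}{n}\,
#'   \frac{|C_1||C_2|}{|C_1|+|C_2|}\, r_{C_1 C_2}^2}
#' are merged repeatedly (ties broken towards the lexicographically
#' smallest pair); community probability profiles are the member averages
#' of the `P^t` rows. Disconnected components are never merged, so the
#' merge count equals `n - #components`. The returned partition is the
#' cut of the merge dendrogram with maximal weighted modularity.
#'
#' @param net a [MetaboliteNetwork-class], igraph object or symmetric
#'   nonnegative adjacency matrix.
#' @param steps random-walk length t (>= 1; default 4).
#' @return a [CommunityPartition-class].
#' @examples
#' ## two triangles joined by a single edge separate at Q = 5/14
#' W <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
#' W[cbind(c(1,1,2,4,4,5,3), c(2,3,3,5,6,6,4))] <- 1
#' W <- pmax(W, t(W))
#' cp <- walktrapCommunities(W)
#' communityMembership(cp)
#' @export
walktrapCommunities <- function(net, steps = 4) {
  W <- .asAdjacency(net)
  if (any(W < 0))
    stop("negative edge weights; build the walk on |rho| ",
         "(weights must be nonnegative)")
  if (steps < 1) stop("steps must be >= 1")
  n <- nrow(W)
  if (n == 0) stop("empty network")
  nodeNames <- rownames(W)
  if (is.null(nodeNames)) nodeNames <- paste0("n", seq_len(n))

  Wwalk <- W
  d <- rowSums(Wwalk)
  iso <- d == 0
  if (any(iso)) {                     # unit self-loop keeps P stochastic
    diag(Wwalk)[iso] <- 1
    d[iso] <- 1
  }
  P <- Wwalk / d
  Pt <- P
  if (steps > 1) for (s in 2:steps) Pt <- Pt %*% P

  ## community state
  maxC <- 2L * n
  probs <- matrix(NA_real_, maxC, n)  # community probability profiles
  probs[seq_len(n), ] <- Pt
  sizes <- integer(maxC); sizes[seq_len(n)] <- 1L
  members <- vector("list", maxC)
  members[seq_len(n)] <- as.list(seq_len(n))
  active <- seq_len(n)
  adj <- W > 0                        # community adjacency
  invd <- 1 / d

  dsig <- function(a, b) {
    diff2 <- (probs[a, ] - probs[b, ])^2
    (sizes[a] * sizes[b]) / (sizes[a] + sizes[b]) *
      sum(diff2 * invd) / n
  }

  ## Delta-sigma matrix over active communities (NA = non-adjacent)
  D <- matrix(NA_real_, maxC, maxC)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (adj[i, j]) D[i, j] <- D[j, i] <- dsig(i, j)

  merges <- matrix(0L, 0, 2)
  dSigma <- numeric(0)
  membNow <- seq_len(n)
  trace <- graphModularity(W, membNow)
  nextId <- n

  repeat {
    sub <- D[active, active, drop = FALSE]
    if (all(is.na(sub))) break
    flat <- which(!is.na(sub))
    best <- flat[which.min(sub[flat])]
    bi <- (best - 1) %% length(active) + 1
    bj <- (best - 1) %/% length(active) + 1
    a <- active[min(bi, bj)]; b <- active[max(bi, bj)]

    nextId <- nextId + 1L
    newId <- nextId
    probs[newId, ] <- (sizes[a] * probs[a, ] + sizes[b] * probs[b, ]) /
      (sizes[a] + sizes[b])
    sizes[newId] <- sizes[a] + sizes[b]
    members[[newId]] <- c(members[[a]], members[[b]])
    merges <- rbind(merges, c(a, b))
    dSigma <- c(dSigma, D[a, b])

    active <- c(setdiff(active, c(a, b)), newId)
    adjNew <- adj[a, ] | adj[b, ]
    adj <- rbind(adj, FALSE)[, , drop = FALSE]
    adj <- cbind(adj, FALSE)
    adj[newId, seq_len(ncol(adj) - 1)] <- adjNew[seq_len(ncol(adj) - 1)]
    adj[seq_len(nrow(adj) - 1), newId] <- adjNew[seq_len(nrow(adj) - 1)]
    adj[newId, newId] <- FALSE
    for (c0 in active) {
      if (c0 != newId && adj[newId, c0])
        D[newId, c0] <- D[c0, newId] <- dsig(newId, c0)
    }
    membNow[members[[newId]]] <- newId
    trace <- c(trace, graphModularity(W, membNow))
  }

  bestCut <- which.max(trace) - 1L
  memb <- .partitionAtCut(n, merges, bestCut)
  names(memb) <- nodeNames

  new("CommunityPartition", nodeNames = nodeNames, merges = merges,
      dSigma = dSigma, modularityTrace = trace,
      bestCut = bestCut, membership = memb)
}

.partitionAtCut <- function(n, merges, nMerges) {
  memb <- seq_len(n)
  if (nMerges > 0) {
    comm <- as.list(seq_len(n))
    for (t in seq_len(nMerges)) {
      a <- merges[t, 1]; b <- merges[t, 2]
      comm[[n + t]] <- c(comm[[a]], comm[[b]])
      comm[[a]] <- comm[[b]] <- integer(0)
      memb[comm[[n + t]]] <- n + t
    }
  }
  as.integer(factor(memb, levels = unique(memb)))
}

#' @rdname walktrapCommunities
#' @param partition a [CommunityPartition-class].
#' @param nMerges number of merges to apply (0 = all singletons).
#' @return `cutPartition()`: named membership vector at the requested cut.
#' @export
cutPartition <- function(partition, nMerges) {
  n <- length(partition@nodeNames)
  if (nMerges < 0 || nMerges > nrow(partition@merges))
    stop("nMerges out of range")
  memb <- .partitionAtCut(n, partition@merges, nMerges)
  setNames(memb, partition@nodeNames)
}
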