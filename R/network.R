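## Signed correlation-network construction, properties, threshold scan.

#' Build the signed correlation network under dual thresholds
#'
#' An edge joins nodes i and j iff `|rho_ij| > rThresh` and
#' `p_ij <= pThresh`. Edge weight is `|rho|`, the sign records the
#' direction of the correlation. Isolated nodes are retained. When
#' `qTarget` is supplied, `pThresh` is derived from the upper-triangle
#' p-values via [pThresholdForQ()], so every edge has BH q <= qTarget
#' (the dual rule "q < 0.05 and r > 0.5" of the original analysis is
#' `buildNetwork(stats, rThresh = 0.5, qTarget = 0.05)`).
#'
#' @param stats a [CorrelationStats-class].
#' @param rThresh correlation-coefficient threshold in `[0, 1]`
#'   (strictly exceeded).
#' @param pThresh p-value threshold in `[0, 1]`; ignored when `qTarget`
#'   is given.
#' @param qTarget optional FDR level from which to derive `pThresh`.
#' @return a [MetaboliteNetwork-class].
#' @examples
#' set.seed(1)
#' cs <- correlationMatrix(matrix(rnorm(60), 12, 5))
#' buildNetwork(cs, rThresh = 0, pThresh = 1)
#' @export
buildNetwork <- function(stats, rThresh = 0.5, pThresh = 0.05,
                         qTarget = NULL) {
  if (!is.null(qTarget))
    pThresh <- pThresholdForQ(stats@pval[upper.tri(stats@pval)], qTarget)
  stopifnot(rThresh >= 0, rThresh <= 1, pThresh >= 0, pThresh <= 1)
  nodes <- data.frame(name = stats@labels, kind = stats@nodeKind,
                      compoundClass = stats@compoundClass,
                      stringsAsFactors = FALSE)
  idx <- which(upper.tri(stats@rho), arr.ind = TRUE)
  rho <- stats@rho[idx]; p <- stats@pval[idx]; q <- stats@qval[idx]
  keep <- !is.na(rho) & !is.na(p) & abs(rho) > rThresh & p <= pThresh
  edges <- data.frame(from = stats@labels[idx[keep, 1]],
                      to = stats@labels[idx[keep, 2]],
                      weight = abs(rho[keep]),
                      sign = sign(rho[keep]),
                      rho = rho[keep], p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  new("MetaboliteNetwork", nodes = nodes, edges = edges,
      thresholds = list(r = rThresh, p = pThresh, qTarget = qTarget),
      netMeta = list())
}

#' Convert a MetaboliteNetwork to an igraph object
#'
#' Nodes carry `kind`, `compoundClass` and `degree` attributes; edges
#' carry `weight` (= |rho|), `sign`, `rho`, `p` and `q`.
#'
#' @param net a [MetaboliteNetwork-class].
#' @return an undirected [igraph::igraph] graph.
#' @export
asIgraph <- function(net) {
  nd <- net@nodes
  nd$degree <- unname(nodeDegree(net))
  nd$compoundClass[is.na(nd$compoundClass)] <- "none"
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = nd)
}

#' Four global network properties
#'
#' Average node degree `2|E|/|V|`, global clustering coefficient
#' (transitivity: three times the triangle count over the number of
#' connected triples), network density `2|E|/(|V|(|V|-1))`, and diameter
#' (longest shortest path in unweighted hops within the largest connected
#' component). Degenerate cases: a graph with fewer than two nodes has
#' density reported as 0 with a warning; a graph without connected
#' triples has clustering 0; an edgeless graph has diameter 0.
#'
#' @param net a [MetaboliteNetwork-class] or igraph object.
#' @return named list: `avgDegree`, `clustering`, `density`, `diameter`.
#' @export
networkProperties <- function(net) {
  g <- if (is(net, "MetaboliteNetwork")) asIgraph(net) else net
  nV <- igraph::vcount(g); nE <- igraph::ecount(g)
  if (nV == 0) stop("network has no nodes")
  avgDegree <- 2 * nE / nV
  density <- if (nV < 2) {
    warning("density undefined for a single-node network; reporting 0")
    0
  } else 2 * nE / (nV * (nV - 1))
  clustering <- igraph::transitivity(g, type = "global")
  if (is.nan(clustering) || is.na(clustering)) clustering <- 0
  diameter <- 0
  if (nE > 0) {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    diameter <- igraph::diameter(sub, weights = NA)
  }
  list(avgDegree = avgDegree, clustering = clustering,
       density = density, diameter = as.numeric(diameter))
}

#' Select the correlation threshold by property robustness
#'
#' For every candidate coefficient threshold r the four network
#' properties are computed at every p-value threshold in the grid (by
#' default the BH thresholds for q = 0.01 ... 0.10). The stability score
#' of r is the worst (largest) normalized range
#' `(max - min) / max(|median|, eps)` across the four property curves;
#' the chosen threshold is the smallest r whose score does not exceed
#' `stabilityTol`. If no r qualifies the score-minimizing r is returned
#' with a warning.
#'
#' @param stats a [CorrelationStats-class].
#' @param rGrid ascending grid of candidate r thresholds.
#' @param qGrid FDR levels from which the p-value grid is derived; used
#'   only when `pGrid` is NULL.
#' @param pGrid optional explicit ascending p-value grid.
#' @param stabilityTol maximal accepted normalized range (> 0).
#' @return list with `rGrid`, `pGrid`, `properties` (long data.frame),
#'   `scores` (per r) and `chosenR`.
#' @export
robustnessScan <- function(stats, rGrid = seq(0.30, 0.95, by = 0.05),
                           qGrid = seq(0.01, 0.10, by = 0.01),
                           pGrid = NULL, stabilityTol = 0.1) {
  if (stabilityTol <= 0) stop("stabilityTol must be > 0")
  if (is.null(pGrid)) {
    pv <- stats@pval[upper.tri(stats@pval)]
    pGrid <- sort(unique(vapply(qGrid, function(q)
      pThresholdForQ(pv, q), 0)))
  }
  rGrid <- sort(unique(rGrid))
  if (!length(rGrid) || !length(pGrid))
    stop("degenerate threshold grids")
  propNames <- c("avgDegree", "clustering", "density", "diameter")
  rows <- list()
  scores <- numeric(length(rGrid))
  eps <- 1e-8
  for (ri in seq_along(rGrid)) {
    mat <- matrix(NA_real_, length(pGrid), 4,
                  dimnames = list(NULL, propNames))
    for (pi in seq_along(pGrid)) {
      net <- suppressWarnings(
        buildNetwork(stats, rThresh = rGrid[ri], pThresh = pGrid[pi]))
      mat[pi, ] <- unlist(suppressWarnings(networkProperties(net)))
    }
    rel <- apply(mat, 2, function(v)
      (max(v) - min(v)) / max(abs(median(v)), eps))
    scores[ri] <- max(rel)
    rows[[ri]] <- data.frame(r = rGrid[ri], p = pGrid, mat)
  }
  qualifying <- which(scores <= stabilityTol)
  if (length(qualifying)) {
    chosenR <- rGrid[min(qualifying)]
  } else {
    warning("no threshold met the stability tolerance; ",
            "returning the score-minimizing r")
    chosenR <- rGrid[which.min(scores)]
  }
  list(rGrid = rGrid, pGrid = pGrid,
       properties = do.call(rbind, rows),
       scores = setNames(scores, rGrid), chosenR = chosenR)
}

#' Export a network as GraphML / SIF for Cytoscape
#'
#' `writeGraphML()` writes a GraphML file with node attributes (kind,
#' compound class, degree) and edge attributes (weight, sign, rho, p, q).
#' `writeSIF()` writes a SIF file (`node1 pp node2`, one line per edge,
#' interaction `pp`/`pn` for positive/negative sign) plus node and edge
#' attribute tables alongside.
#'
#' @param net a [MetaboliteNetwork-class].
#' @param path output path (for SIF, the `.sif` path; attribute tables
#'   get `_nodes.csv` / `_edges.csv` suffixes).
#' @return invisibly, the path(s) written.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname writeGraphML
#' @export
writeSIF <- function(net, path) {
  ed <- net@edges
  lines <- if (nrow(ed))
    paste(ed$from, ifelse(ed$sign > 0, "pp", "pn"), ed$to) else character()
  writeLines(lines, path)
  base <- sub("\\.sif$", "", path)
  nd <- net@nodes
  nd$degree <- unname(nodeDegree(net))
  write.csv(nd, paste0(base, "_nodes.csv"), row.names = FALSE)
  write.csv(ed, paste0(base, "_edges.csv"), row.names = FALSE)
  invisible(c(path, paste0(base, "_nodes.csv"), paste0(base, "_edges.csv")))
}
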