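## Trait-neighborhood subgraphs, correlation-sign summaries, and edge
## commonality between two state networks.

#' Extract the subgraph adjacent to a physiological trait
#'
#' Returns the induced subnetwork on the trait node and its direct
#' neighbors: the signed trait--neighbor edges plus all induced
#' neighbor--neighbor edges. Node degree (for node-size scaling in
#' Cytoscape-style renderings) is written by the exporters.
#'
#' @param net a [MetaboliteNetwork-class] containing the trait node.
#' @param trait trait node name (e.g. `"survival"`).
#' @return a [MetaboliteNetwork-class] restricted to the neighborhood;
#'   its `netMeta$trait` records the focal trait.
#' @export
traitSubgraph <- function(net, trait) {
  if (!trait %in% net@nodes$name)
    stop("trait node '", trait, "' not present in the network")
  ed <- net@edges
  nb <- unique(c(ed$to[ed$from == trait], ed$from[ed$to == trait]))
  keep <- c(trait, sort(nb))
  sub <- induceSubnetwork(net, keep)
  sub@netMeta$trait <- trait
  sub
}

#' @rdname traitSubgraph
#' @param nodes node names to keep.
#' @return `induceSubnetwork()`: the induced subnetwork on `nodes`.
#' @export
induceSubnetwork <- function(net, nodes) {
  miss <- setdiff(nodes, net@nodes$name)
  if (length(miss))
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  nd <- net@nodes[net@nodes$name %in% nodes, , drop = FALSE]
  rownames(nd) <- NULL
  ed <- net@edges
  ed <- ed[ed$from %in% nodes & ed$to %in% nodes, , drop = FALSE]
  rownames(ed) <- NULL
  new("MetaboliteNetwork", nodes = nd, edges = ed,
      thresholds = net@thresholds, netMeta = net@netMeta)
}

#' Summarize the signs of a trait's correlations
#'
#' Counts the positive and negative edges between the focal trait and its
#' neighbors, optionally grouped by compound class (trait neighbors, e.g.
#' the other trait, are grouped under class `"trait"`). The grand totals
#' equal the trait's degree in the parent network.
#'
#' @param sub a trait subgraph from [traitSubgraph()].
#' @param byClass group counts by compound class (default TRUE).
#' @return data.frame: class (when `byClass`), nPositive, nNegative.
#' @export
signSummary <- function(sub, byClass = TRUE) {
  trait <- sub@netMeta$trait
  if (is.null(trait))
    stop("not a trait subgraph; run traitSubgraph() first")
  ed <- sub@edges
  ed <- ed[ed$from == trait | ed$to == trait, , drop = FALSE]
  other <- ifelse(ed$from == trait, ed$to, ed$from)
  cls <- sub@nodes$compoundClass[match(other, sub@nodes$name)]
  kind <- sub@nodes$kind[match(other, sub@nodes$name)]
  cls[kind == "trait"] <- "trait"
  if (!byClass) {
    return(data.frame(nPositive = sum(ed$sign > 0),
                      nNegative = sum(ed$sign < 0)))
  }
  if (!nrow(ed))
    return(data.frame(class = character(), nPositive = integer(),
                      nNegative = integer()))
  out <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    sel <- cls == cl
    data.frame(class = cl, nPositive = sum(ed$sign[sel] > 0),
               nNegative = sum(ed$sign[sel] < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Edge commonality between two networks
#'
#' Shared edges are the unordered node-pair intersection of the two edge
#' sets; correlation signs are compared on the shared edges and
#' mismatches flagged (reported, not dropped). The Jaccard index is
#' |shared| / |union|.
#'
#' @param netA,netB two [MetaboliteNetwork-class] objects over comparable
#'   node name spaces.
#' @return list: `shared` (data.frame: from, to, signA, signB,
#'   signMismatch), `nA`, `nB`, `jaccard`.
#' @export
networkOverlap <- function(netA, netB) {
  keyOf <- function(ed)
    if (nrow(ed)) paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to),
                        sep = "|") else character()
  edA <- netA@edges; edB <- netB@edges
  kA <- keyOf(edA); kB <- keyOf(edB)
  shared <- intersect(kA, kB)
  uni <- union(kA, kB)
  jac <- if (length(uni)) length(shared) / length(uni) else 0
  if (length(shared)) {
    iA <- match(shared, kA); iB <- match(shared, kB)
    sh <- data.frame(
      from = pmin(edA$from[iA], edA$to[iA]),
      to = pmax(edA$from[iA], edA$to[iA]),
      signA = edA$sign[iA], signB = edB$sign[iB])
    sh$signMismatch <- sh$signA != sh$signB
  } else {
    sh <- data.frame(from = character(), to = character(),
                     signA = numeric(), signB = numeric(),
                     signMismatch = logical())
  }
  list(shared = sh, nA = length(kA), nB = length(kB), jaccard = jac)
}
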