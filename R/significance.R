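## Community cohesiveness test: paired comparison of each member node's
## within-community degree against its residual degree once all
## intra-community edges are deleted, via a Wilcoxon signed-rank test.

#' Tie-aware Wilcoxon signed-rank test
#'
#' Two-sided (or one-sided) signed-rank test on paired differences.
#' Zero differences are dropped (classic Wilcoxon convention); |d| are
#' ranked with mid-ranks. For up to `exactLimit` nonzero pairs the exact
#' sign-flip null distribution of the positive-rank sum is computed by a
#' convolution over the (doubled, hence integer) ranks, which remains
#' exact under ties; beyond that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exactLimit maximal number of nonzero pairs for the exact null.
#' @return list: `statistic` (positive-rank sum V), `pValue`, `nNonzero`,
#'   `nZeroDropped`, `exact`, `degenerate` (TRUE when all differences are
#'   zero, in which case p = 1).
#' @examples
#' wilcoxonSignedRank(rep(8, 10))$pValue   # 2/1024
#' @export
wilcoxonSignedRank <- function(d, alternative = c("two.sided", "greater",
                                                  "less"),
                               exactLimit = 25) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  nZero <- length(d) - length(nz)
  if (!length(nz))
    return(list(statistic = NA_real_, pValue = 1, nNonzero = 0L,
                nZeroDropped = nZero, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  n <- length(nz)
  if (n <= exactLimit) {
    r2 <- as.integer(round(2 * r))          # doubled mid-ranks: integers
    total <- sum(r2)
    f <- numeric(total + 1); f[1] <- 1
    for (w in r2) {
      g <- f / 2
      g[(w + 1):(total + 1)] <- g[(w + 1):(total + 1)] +
        f[seq_len(total + 1 - w)] / 2
      f <- g
    }
    v2 <- round(2 * V)
    pGE <- sum(f[(v2 + 1):(total + 1)])
    pLE <- sum(f[seq_len(v2 + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pGE, pLE)),
                greater = pGE,
                less = pLE)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- 0.5
    zGE <- (V - mu - cc) / sqrt(sig2)
    zLE <- (V - mu + cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(zGE, lower.tail = FALSE),
                                           pnorm(zLE))),
                greater = pnorm(zGE, lower.tail = FALSE),
                less = pnorm(zLE))
    exact <- FALSE
  }
  list(statistic = V, pValue = p, nNonzero = n, nZeroDropped = nZero,
       exact = exact, degenerate = FALSE)
}

#' Internal and residual degrees of a community's nodes
#'
#' For every node of the community: `internal` is its degree in the
#' isolated community subgraph; `residual` is its degree in the full
#' network after all intra-community edges have been deleted. By
#' construction `internal + residual` equals the node's degree in the
#' full network.
#'
#' @param net a [MetaboliteNetwork-class].
#' @param membership named community assignment covering all nodes.
#' @param community the community id to extract.
#' @return data.frame: node, internal, residual.
#' @export
communityDegrees <- function(net, membership, community) {
  nodeNames <- net@nodes$name
  if (!is.null(names(membership))) {
    if (!all(nodeNames %in% names(membership)))
      stop("membership is missing node(s): ",
           paste(setdiff(nodeNames, names(membership)), collapse = ", "))
    memb <- membership[nodeNames]
  } else {
    if (length(membership) != length(nodeNames))
      stop("membership must assign every node to exactly one community")
    memb <- setNames(membership, nodeNames)
  }
  inC <- names(memb)[memb == community]
  if (!length(inC)) stop("no nodes in community ", community)
  ed <- net@edges
  fromIn <- ed$from %in% inC
  toIn <- ed$to %in% inC
  intra <- fromIn & toIn
  internal <- setNames(integer(length(inC)), inC)
  residual <- setNames(integer(length(inC)), inC)
  if (any(intra)) {
    t1 <- table(ed$from[intra]); t2 <- table(ed$to[intra])
    internal[names(t1)] <- internal[names(t1)] + as.integer(t1)
    internal[names(t2)] <- internal[names(t2)] + as.integer(t2)
  }
  inter <- xor(fromIn, toIn)
  if (any(inter)) {
    ends <- c(ed$from[inter], ed$to[inter])
    ends <- ends[ends %in% inC]
    t3 <- table(ends)
    residual[names(t3)] <- residual[names(t3)] + as.integer(t3)
  }
  data.frame(node = inC, internal = unname(internal),
             residual = unname(residual), stringsAsFactors = FALSE)
}

#' Significance of detected communities
#'
#' For every community larger than `minSize` nodes (default: more than
#' nine), tests whether its nodes are more strongly connected inside the
#' community than to the rest of the network: a Wilcoxon signed-rank test
#' on the paired (internal degree, residual degree) samples per node.
#' Smaller communities are reported untested. A community whose nodes
#' have identical internal and residual degrees is degenerate and
#' reported with p = 1.
#'
#' @param net a [MetaboliteNetwork-class].
#' @param membership named community assignment (e.g.
#'   [communityMembership()] of a walktrap partition).
#' @param minSize communities must exceed this size to be tested.
#' @param alternative sidedness of the test (default two-sided).
#' @return data.frame with one row per community: community, size,
#'   tested, statistic, pValue, nZeroDropped, degenerate.
#' @export
communitySignificance <- function(net, membership, minSize = 9,
                                  alternative = "two.sided") {
  memb <- .alignMembership(membership, net@nodes$name,
                           nrow(net@nodes))
  ids <- sort(unique(memb))
  rows <- lapply(ids, function(c0) {
    size <- sum(memb == c0)
    if (size <= minSize)
      return(data.frame(community = c0, size = size, tested = FALSE,
                        statistic = NA_real_, pValue = NA_real_,
                        nZeroDropped = NA_integer_, degenerate = FALSE))
    deg <- communityDegrees(net, memb, c0)
    tst <- wilcoxonSignedRank(deg$internal - deg$residual,
                              alternative = alternative)
    data.frame(community = c0, size = size, tested = TRUE,
               statistic = tst$statistic, pValue = tst$pValue,
               nZeroDropped = tst$nZeroDropped,
               degenerate = tst$degenerate)
  })
  do.call(rbind, rows)
}
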