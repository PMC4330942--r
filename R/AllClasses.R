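## Central S4 containers.

#' AbundanceTable: samples x metabolites relative abundances
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] storing
#' relative metabolite abundances (assay \code{"abundance"}, metabolites as
#' rows, samples as columns), per-sample metadata (\code{month},
#' \code{state}, \code{replicate}) and per-metabolite metadata
#' (\code{compound_class}).
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("month", "state", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    key <- paste(cd$month, cd$state, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (month, state, replicate) sample triples")
    if (!all(as.character(cd$state) %in% .SEED_STATES))
      msg <- c(msg, paste0("state must be one of: ",
                           paste(.SEED_STATES, collapse = ", ")))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated metabolite names")
  if (!"compound_class" %in% colnames(rowData(object)))
    msg <- c(msg, "missing metabolite metadata column: compound_class")
  a <- assay(object, "abundance")
  if (any(is.infinite(a)))
    msg <- c(msg, "abundance values must be finite (use NA for missing)")
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "abundance values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, samples in rows, metabolites in columns;
#'   column names are metabolite names. Missing measurements are `NA`,
#'   never silent zeros.
#' @param sampleData data.frame with columns `month` (abbreviations as in
#'   [monthCycle()]), `state` (`dry`, `germinated` or `dehydrated`) and
#'   `replicate`, one row per sample row of `values`.
#' @param metaboliteData data.frame with column `compound_class`, one row
#'   per metabolite (default class `"other"`).
#' @return An [AbundanceTable-class] object.
#' @examples
#' v <- matrix(runif(8, 1, 5), 4, 2, dimnames = list(NULL, c("glucose", "proline")))
#' sd <- data.frame(month = c("Jun", "Jun", "Jul", "Jul"),
#'                  state = "dry", replicate = c(1, 2, 1, 2))
#' at <- AbundanceTable(v, sd)
#' abundanceValues(at)
#' @export
AbundanceTable <- function(values, sampleData,
                           metaboliteData = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' needs metabolite names as column names")
  storage.mode(values) <- "double"
  sampleData <- as.data.frame(sampleData)
  sampleData$month <- .monthFactor(sampleData$month)
  sampleData$state <- as.character(sampleData$state)
  if (is.null(metaboliteData))
    metaboliteData <- data.frame(compound_class =
                                   rep("other", ncol(values)))
  rd <- DataFrame(metaboliteData, row.names = colnames(values))
  se <- SummarizedExperiment(
    assays = list(abundance = t(values)),
    colData = DataFrame(sampleData),
    rowData = rd)
  colnames(se) <- paste(sampleData$month, sampleData$state,
                        sampleData$replicate, sep = "_")
  new("AbundanceTable", se)
}

#' @rdname AbundanceTable
#' @param x an AbundanceTable
#' @return `abundanceValues()`: the samples x metabolites matrix.
#' @export
abundanceValues <- function(x) t(assay(x, "abundance"))

#' @rdname AbundanceTable
#' @return `sampleData()`: sample metadata as a data.frame.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @rdname AbundanceTable
#' @return `metaboliteClass()`: named character of compound classes.
#' @export
metaboliteClass <- function(x)
  setNames(as.character(rowData(x)$compound_class), rownames(x))

#' @rdname AbundanceTable
#' @param state seed state to keep
#' @return `subsetState()`: AbundanceTable restricted to one seed state.
#' @export
subsetState <- function(x, state) {
  state <- match.arg(state, .SEED_STATES)
  x[, colData(x)$state == state]
}

#' @rdname AbundanceTable
#' @return `monthlyMeans()`: months x metabolites matrix of replicate means
#'   (rows ordered as [monthCycle()], restricted to months present).
#' @export
monthlyMeans <- function(x, state = NULL) {
  if (!is.null(state)) x <- subsetState(x, state)
  if (length(unique(colData(x)$state)) > 1L)
    stop("table mixes seed states; pass 'state=' to select one")
  v <- abundanceValues(x)
  mo <- droplevels(colData(x)$month)
  out <- rowsum(v, group = mo, reorder = TRUE) /
    as.vector(table(mo))
  # rowsum propagates NA; recompute columns containing NA with na.rm
  if (anyNA(out)) {
    for (j in which(colSums(is.na(out)) > 0)) {
      out[, j] <- tapply(v[, j], mo, mean, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
  }
  out
}

setMethod("show", "AbundanceTable", function(object) {
  cd <- colData(object)
  cat("AbundanceTable:", nrow(object), "metabolites x",
      ncol(object), "samples\n")
  cat("  states:", paste(unique(cd$state), collapse = ", "), "\n")
  cat("  months:", length(unique(cd$month)), " replicates:",
      length(unique(cd$replicate)), "\n")
  cat("  classes:",
      paste(head(unique(as.character(rowData(object)$compound_class)), 5),
            collapse = ", "), "...\n")
})

#' TraitSeries: monthly germination and survival counts
#'
#' Replicate-level counts of germinated / surviving seeds out of a fixed
#' number (50 in the original design), stored long: one row per
#' (month, trait, replicate).
#'
#' @slot counts data.frame with columns month, trait, replicate,
#'   successes, n.
#' @export
setClass("TraitSeries", representation(counts = "data.frame"))

setValidity("TraitSeries", function(object) {
  d <- object@counts
  msg <- character()
  need <- c("month", "trait", "replicate", "successes", "n")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (!all(d$trait %in% c("germination", "survival")))
    msg <- c(msg, "trait must be 'germination' or 'survival'")
  if (any(d$successes < 0 | d$successes > d$n))
    msg <- c(msg, "successes must lie in [0, n]")
  if (anyDuplicated(d[, c("month", "trait", "replicate")]))
    msg <- c(msg, "duplicated (month, trait, replicate) rows")
  if (length(msg)) msg else TRUE
})

#' Construct a TraitSeries
#'
#' @param counts data.frame with columns `month`, `trait` (`germination` or
#'   `survival`), `replicate`, `successes`, `n` (seeds per replicate,
#'   typically 50).
#' @return A [TraitSeries-class] object.
#' @export
TraitSeries <- function(counts) {
  counts <- as.data.frame(counts)
  counts$month <- .monthFactor(counts$month)
  counts$trait <- as.character(counts$trait)
  new("TraitSeries", counts = counts)
}

#' @rdname TraitSeries
#' @param x a TraitSeries
#' @return `traitCounts()`: the underlying data.frame with a derived
#'   `percentage` column.
#' @export
traitCounts <- function(x) {
  d <- x@counts
  d$percentage <- 100 * d$successes / d$n
  d
}

#' @rdname TraitSeries
#' @return `traitMonthlyPercent()`: months x traits matrix of mean
#'   percentages across replicates.
#' @export
traitMonthlyPercent <- function(x) {
  d <- traitCounts(x)
  months <- levels(droplevels(d$month))
  traits <- sort(unique(d$trait))
  out <- matrix(NA_real_, length(months), length(traits),
                dimnames = list(months, traits))
  agg <- aggregate(percentage ~ month + trait, data = d, FUN = mean)
  out[cbind(as.character(agg$month), agg$trait)] <- agg$percentage
  out
}

setMethod("show", "TraitSeries", function(object) {
  d <- traitCounts(object)
  cat("TraitSeries:", length(unique(d$month)), "months x",
      length(unique(d$trait)), "traits,",
      length(unique(d$replicate)), "replicates of n =",
      unique(d$n)[1], "seeds\n")
  print(round(traitMonthlyPercent(object), 1))
})

#' CorrelationStats: all-pairs correlation matrices
#'
#' Symmetric matrices of correlation coefficient, p-value and
#' Benjamini-Hochberg q-value over metabolites plus traits, with the
#' pairwise sample counts actually used.
#'
#' @slot labels ordered node names (metabolites then traits).
#' @slot rho,pval,qval,nUsed symmetric matrices.
#' @slot method "spearman" or "pearson".
#' @slot pMethod p-value method used ("exact" or "t").
#' @slot nodeKind "metabolite" or "trait" per label.
#' @slot compoundClass compound class per label (NA for traits).
#' @export
setClass("CorrelationStats",
         representation(labels = "character", rho = "matrix",
                        pval = "matrix", qval = "matrix",
                        nUsed = "matrix", method = "character",
                        pMethod = "character", nodeKind = "character",
                        compoundClass = "character"))

setValidity("CorrelationStats", function(object) {
  msg <- character()
  r <- object@rho
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-10, check.attributes = FALSE)))
    msg <- c(msg, "rho must be symmetric")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "|rho| must be <= 1")
  if (any(abs(diag(r) - 1) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal rho must be 1")
  off <- upper.tri(r)
  pq <- object@qval[off] + 1e-12 < object@pval[off]
  if (any(pq, na.rm = TRUE))
    msg <- c(msg, "qval must be >= pval elementwise (BH)")
  if (length(object@labels) != nrow(r))
    msg <- c(msg, "labels length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationStats", function(object) {
  nv <- length(object@labels)
  nt <- sum(object@nodeKind == "trait")
  cat("CorrelationStats (", object@method, ", p: ", object@pMethod, "): ",
      nv, " nodes (", nv - nt, " metabolites + ", nt, " traits)\n", sep = "")
  q <- object@qval[upper.tri(object@qval)]
  cat("  pairs:", sum(!is.na(q)), " with q <= 0.05:",
      sum(q <= 0.05, na.rm = TRUE), "\n")
})

#' @rdname CorrelationStats-class
#' @param object a CorrelationStats
#' @return `corLabels()`: node labels; `corRho()`, `corPval()`, `corQval()`,
#'   `corNUsed()`: the corresponding matrices.
#' @export
corLabels <- function(object) object@labels
#' @rdname CorrelationStats-class
#' @export
corRho <- function(object) object@rho
#' @rdname CorrelationStats-class
#' @export
corPval <- function(object) object@pval
#' @rdname CorrelationStats-class
#' @export
corQval <- function(object) object@qval
#' @rdname CorrelationStats-class
#' @export
corNUsed <- function(object) object@nUsed

#' MetaboliteNetwork: signed weighted correlation network
#'
#' Undirected graph whose nodes are metabolites or physiological traits and
#' whose edges carry the correlation they were built from: weight = |rho|,
#' sign = sign(rho). No self-loops, no multi-edges.
#'
#' @slot nodes data.frame: name, kind ("metabolite"/"trait"),
#'   compoundClass.
#' @slot edges data.frame: from, to, weight, sign, rho, p, q.
#' @slot thresholds list with elements r, p (and optionally qTarget) the
#'   network was built with.
#' @slot netMeta free-form list (e.g. trait name for trait subgraphs).
#' @export
setClass("MetaboliteNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        thresholds = "list", netMeta = "list"))

setValidity("MetaboliteNetwork", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("name", "kind", "compoundClass") %in% colnames(nd)))
    msg <- c(msg, "nodes need columns name, kind, compoundClass")
  if (anyDuplicated(nd$name))
    msg <- c(msg, "duplicated node names")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$name))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(ed$from == ed$to))
      msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    if (anyDuplicated(key))
      msg <- c(msg, "multi-edges are not allowed")
    if (any(ed$weight <= 0 | ed$weight > 1))
      msg <- c(msg, "edge weight must lie in (0, 1]")
    if (any(abs(ed$sign * ed$weight - ed$rho) > 1e-9))
      msg <- c(msg, "sign * weight must equal rho")
    th <- object@thresholds
    if (!is.null(th$r) && any(ed$weight <= th$r - 1e-12))
      msg <- c(msg, "edges must satisfy |rho| > r threshold")
    if (!is.null(th$p) && any(ed$p > th$p + 1e-15))
      msg <- c(msg, "edges must satisfy p <= p threshold")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MetaboliteNetwork-class
#' @param object a MetaboliteNetwork
#' @return `networkNodes()` / `networkEdges()`: the node / edge tables;
#'   `nodeDegree()`: named unweighted degree vector.
#' @export
networkNodes <- function(object) object@nodes
#' @rdname MetaboliteNetwork-class
#' @export
networkEdges <- function(object) object@edges
#' @rdname MetaboliteNetwork-class
#' @export
nodeDegree <- function(object) {
  deg <- setNames(integer(nrow(object@nodes)), object@nodes$name)
  ed <- object@edges
  if (nrow(ed)) {
    t1 <- table(ed$from); t2 <- table(ed$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

setMethod("show", "MetaboliteNetwork", function(object) {
  cat("MetaboliteNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  th <- object@thresholds
  if (length(th))
    cat("  thresholds: |rho| >", th$r, ", p <=", signif(th$p, 3),
        if (!is.null(th$qTarget)) paste0("(q <= ", th$qTarget, ")"), "\n")
  if (nrow(object@edges)) {
    cat("  signs: ", sum(object@edges$sign > 0), " positive / ",
        sum(object@edges$sign < 0), " negative\n", sep = "")
  }
})

#' CommunityPartition: walktrap merge dendrogram and best cut
#'
#' Result of agglomerative random-walk community detection: the full merge
#' sequence, the increase in mean squared random-walk distance at each
#' merge, the modularity after each merge, and the modularity-maximizing
#' cut.
#'
#' @slot nodeNames node names in network order.
#' @slot merges k x 2 integer matrix; communities 1..n are the singletons,
#'   merge i creates community n + i.
#' @slot dSigma squared-distance increase at each merge.
#' @slot modularityTrace modularity of the partition after 0, 1, ..., k
#'   merges (length k + 1).
#' @slot bestCut number of merges applied at the modularity maximum.
#' @slot membership named integer node -> community at the best cut,
#'   communities renumbered 1..K by first appearance.
#' @export
setClass("CommunityPartition",
         representation(nodeNames = "character", merges = "matrix",
                        dSigma = "numeric", modularityTrace = "numeric",
                        bestCut = "integer", membership = "integer"))

setValidity("CommunityPartition", function(object) {
  msg <- character()
  n <- length(object@nodeNames)
  if (length(object@membership) != n)
    msg <- c(msg, "membership must cover every node")
  if (length(object@modularityTrace) != nrow(object@merges) + 1L)
    msg <- c(msg, "modularity trace must have one entry per cut")
  q <- object@modularityTrace
  if (any(q < -0.5 - 1e-9 | q > 1 + 1e-9))
    msg <- c(msg, "modularity must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname CommunityPartition-class
#' @param object a CommunityPartition
#' @return `communityMembership()`: named integer vector node -> community
#'   at the modularity-maximizing cut; `communitySizes()`: community size
#'   table; `mergeOrder()`: the merge matrix; `modularityTrace()`: the
#'   modularity after each merge.
#' @export
communityMembership <- function(object) object@membership
#' @rdname CommunityPartition-class
#' @export
communitySizes <- function(object) table(object@membership)
#' @rdname CommunityPartition-class
#' @export
mergeOrder <- function(object) object@merges
#' @rdname CommunityPartition-class
#' @export
modularityTrace <- function(object) object@modularityTrace

setMethod("show", "CommunityPartition", function(object) {
  k <- length(unique(object@membership))
  cat("CommunityPartition:", length(object@nodeNames), "nodes ->", k,
      "communities (best cut after", object@bestCut, "of",
      nrow(object@merges), "merges, Q =",
      round(max(object@modularityTrace), 4), ")\n")
  print(communitySizes(object))
})
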