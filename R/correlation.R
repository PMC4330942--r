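## Normality screening, all-pairs rank correlation, FDR edge thresholding.

#' Shapiro-Wilk normality screen
#'
#' Tests every variable for normality across its time-point values and
#' reports the fraction of variables violating the assumption at level
#' `alpha`. When more than half the variables violate normality the
#' recommended correlation method is Spearman's rank correlation,
#' otherwise Pearson.
#'
#' @param x numeric matrix, variables in columns (>= 3 rows).
#' @param alpha significance level for the per-variable test.
#' @return list with `table` (variable, W, p, violated),
#'   `violationFraction` and `recommended` ("spearman" or "pearson").
#' @examples
#' set.seed(1)
#' normalityScreen(matrix(rnorm(60), 12, 5))$recommended
#' @export
normalityScreen <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("normality screen needs >= 3 observations")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][!is.na(x[, j])]
    if (length(v) < 3 || length(unique(v)) == 1L)
      return(c(W = NA_real_, p = NA_real_))
    sw <- shapiro.test(v)
    c(W = unname(sw$statistic), p = sw$p.value)
  })
  tab <- data.frame(variable = nm,
                    W = vapply(res, `[[`, 0, "W"),
                    p = vapply(res, `[[`, 0, "p"))
  tab$violated <- !is.na(tab$p) & tab$p < alpha
  frac <- mean(tab$violated[!is.na(tab$p)])
  list(table = tab,
       violationFraction = frac,
       recommended = if (frac > 0.5) "spearman" else "pearson")
}

#' All-pairs correlation with p- and q-values
#'
#' Computes the symmetric correlation matrix over all variables
#' (metabolites, optionally followed by traits), two-sided p-values, and
#' Benjamini-Hochberg q-values over the upper triangle. Spearman's rho is
#' the Pearson correlation of average-ranked data (ties receive mid-ranks);
#' observations are used pairwise-complete.
#'
#' P-value methods: `"exact"` (default) uses the exact permutation null of
#' Spearman's S, computed by dynamic programming, for tie-free pairs with
#' n <= 12, falling back to the t-approximation otherwise; `"t"` always
#' uses the t-approximation with df = n - 2; `"permutation"` enumerates
#' all permutations (tie-aware, n <= 9 only).
#'
#' Constant variables have undefined correlations: their pairs are
#' recorded as missing and excluded from the multiple-testing correction,
#' with a warning.
#'
#' @param x numeric matrix, samples in rows, variables in columns (>= 4
#'   paired observations per pair).
#' @param method "spearman" (default) or "pearson".
#' @param pMethod "exact", "t" or "permutation" (Spearman only).
#' @param nodeKind optional character vector ("metabolite"/"trait") per
#'   column; defaults to all "metabolite".
#' @param compoundClass optional compound class per column.
#' @return a [CorrelationStats-class].
#' @examples
#' set.seed(1)
#' cs <- correlationMatrix(matrix(rnorm(48), 12, 4))
#' corRho(cs)[1, 2]
#' @export
correlationMatrix <- function(x, method = c("spearman", "pearson"),
                              pMethod = c("exact", "t", "permutation"),
                              nodeKind = NULL, compoundClass = NULL) {
  method <- match.arg(method)
  pMethod <- match.arg(pMethod)
  x <- as.matrix(x)
  nv <- ncol(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- colnames(x) <- paste0("V", seq_len(nv))
  if (is.null(nodeKind)) nodeKind <- rep("metabolite", nv)
  if (is.null(compoundClass)) compoundClass <- rep(NA_character_, nv)

  nUsed <- crossprod(!is.na(x))
  if (any(nUsed[upper.tri(nUsed)] < 4))
    stop("every pair needs >= 4 paired observations")

  constant <- vapply(seq_len(nv), function(j) {
    v <- x[, j][!is.na(x[, j])]
    length(unique(v)) <= 1L
  }, TRUE)
  if (any(constant))
    warning("constant variable(s), correlations recorded as missing: ",
            paste(nm[constant], collapse = ", "))

  rho <- suppressWarnings(
    cor(x, method = method, use = "pairwise.complete.obs"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1

  n <- nrow(x)
  complete <- !anyNA(x)
  pval <- matrix(NA_real_, nv, nv, dimnames = dimnames(rho))
  usedP <- pMethod

  if (method == "pearson") {
    off <- upper.tri(pval)
    pval[off] <- .spearmanTP(rho[off], nUsed[off])   # same t form for Pearson r
    usedP <- "t"
  } else if (pMethod == "t") {
    off <- upper.tri(pval)
    pval[off] <- .spearmanTP(rho[off], nUsed[off])
  } else if (pMethod == "permutation") {
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      if (constant[i] || constant[j]) next
      cc <- complete.cases(x[, i], x[, j])
      pval[i, j] <- .spearmanPermutationP(x[cc, i], x[cc, j])
    }
  } else {
    # exact DP null where valid (tie-free, n <= 12), t-approximation else
    hasTies <- vapply(seq_len(nv), function(j) {
      v <- x[, j][!is.na(x[, j])]
      anyDuplicated(v) > 0L
    }, TRUE)
    tFallback <- FALSE
    if (complete && n <= 12 && !any(hasTies) && !any(constant)) {
      off <- upper.tri(pval)
      S <- (1 - rho[off]) * (n^3 - n) / 6
      pval[off] <- .spearmanExactP(S, n)
      pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
      diag(pval) <- 0
      return(.finishStats(x, rho, pval, nUsed, nm, method, "exact",
                          nodeKind, compoundClass))
    }
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      if (constant[i] || constant[j]) next
      if (complete && !hasTies[i] && !hasTies[j] && n <= 12) {
        S <- (1 - rho[i, j]) * (n^3 - n) / 6
        pval[i, j] <- .spearmanExactP(S, n)
      } else {
        cc <- complete.cases(x[, i], x[, j])
        xi <- x[cc, i]; yj <- x[cc, j]
        m <- length(xi)
        tieFree <- m <= 12 && !anyDuplicated(xi) && !anyDuplicated(yj)
        if (tieFree && m >= 4) {
          S <- sum((rank(xi) - rank(yj))^2)
          pval[i, j] <- .spearmanExactP(S, m)
        } else {
          pval[i, j] <- .spearmanTP(rho[i, j], m)
          tFallback <- TRUE
        }
      }
    }
    if (tFallback) usedP <- "exact+t"
  }

  pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
  diag(pval) <- 0
  .finishStats(x, rho, pval, nUsed, nm, method, usedP, nodeKind,
               compoundClass)
}

## BH q-values over the upper triangle and object assembly
.finishStats <- function(x, rho, pval, nUsed, nm, method, usedP,
                         nodeKind, compoundClass) {
  nv <- ncol(x)
  qval <- matrix(NA_real_, nv, nv, dimnames = dimnames(rho))
  off <- upper.tri(qval)
  pv <- pval[off]
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- p.adjust(pv[ok], method = "BH")
  qval[off] <- qv
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(qval) <- 0
  new("CorrelationStats", labels = nm, rho = rho, pval = pval,
      qval = qval, nUsed = nUsed, method = method, pMethod = usedP,
      nodeKind = nodeKind, compoundClass = compoundClass)
}

#' Benjamini-Hochberg p-value threshold for a target q-value
#'
#' Sorts the p-values ascending and returns the largest p(k) with
#' p(k) <= qTarget * k / m (0 when no p-value qualifies). Every test with
#' p <= the returned threshold has BH-adjusted q <= qTarget.
#'
#' @param pvals p-values in `[0, 1]` (NA dropped).
#' @param qTarget target FDR level in (0, 1).
#' @return the p-value threshold ensuring q <= qTarget.
#' @examples
#' pThresholdForQ(c(0.001, 0.01, 0.02, 0.2, 0.5), 0.05)   # 0.02
#' @export
pThresholdForQ <- function(pvals, qTarget = 0.05) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values supplied")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (qTarget <= 0 || qTarget >= 1) stop("qTarget must lie in (0, 1)")
  m <- length(pvals)
  sp <- sort(pvals)
  ok <- which(sp <= qTarget * seq_len(m) / m)
  if (!length(ok)) 0 else sp[max(ok)]
}

#' Assemble the analysis matrix of monthly metabolite and trait values
#'
#' Applies the preprocessing chain in its canonical order for one seed
#' state: per-metabolite mean normalization of the monthly means, arcsine
#' transformation of the trait percentages, then pareto scaling of
#' everything. The result is the months x (metabolites + traits) matrix
#' the correlation analysis runs on. Metabolites missing in more than
#' half the months are dropped with a warning.
#'
#' Note that all three transforms are monotone per variable, so
#' Spearman's rank correlation is unaffected by them; they matter for
#' Pearson correlation and for any visualisation of the matrix.
#'
#' @param abundance an [AbundanceTable-class].
#' @param traits a [TraitSeries-class] or NULL (metabolites only).
#' @param state seed state to analyse.
#' @return list with `matrix` (months x variables), `nodeKind` and
#'   `compoundClass` aligned to its columns.
#' @export
prepareAnalysisMatrix <- function(abundance, traits = NULL,
                                  state = "dehydrated") {
  mm <- monthlyMeans(abundance, state = state)
  missFrac <- colMeans(is.na(mm))
  drop <- missFrac > 0.5
  if (any(drop)) {
    warning("dropping metabolite(s) missing in > 50% of months: ",
            paste(colnames(mm)[drop], collapse = ", "))
    mm <- mm[, !drop, drop = FALSE]
  }
  mm <- meanNormalize(mm)
  cls <- metaboliteClass(abundance)[colnames(mm)]
  kinds <- rep("metabolite", ncol(mm))
  if (!is.null(traits)) {
    tp <- traitMonthlyPercent(traits)
    tp <- tp[rownames(mm), , drop = FALSE]
    tt <- apply(tp, 2, arcsinTransform)
    mm <- cbind(mm, tt)
    kinds <- c(kinds, rep("trait", ncol(tt)))
    cls <- c(cls, setNames(rep(NA_character_, ncol(tt)), colnames(tt)))
  }
  mat <- paretoScale(mm)
  list(matrix = mat, nodeKind = kinds, compoundClass = unname(cls))
}

#' Write correlations in long format
#'
#' One row per unordered pair: node_i, node_j, rho, p, q, n.
#'
#' @param stats a [CorrelationStats-class].
#' @param path output CSV path.
#' @return invisibly, the long-format data.frame.
#' @export
writeCorrelations <- function(stats, path) {
  nv <- length(stats@labels)
  idx <- which(upper.tri(stats@rho), arr.ind = TRUE)
  d <- data.frame(node_i = stats@labels[idx[, 1]],
                  node_j = stats@labels[idx[, 2]],
                  rho = stats@rho[idx],
                  p = stats@pval[idx],
                  q = stats@qval[idx],
                  n = stats@nUsed[idx])
  d <- d[order(d$node_i, d$node_j), ]
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}
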