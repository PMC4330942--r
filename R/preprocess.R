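## Data transformations applied ahead of the correlation analysis.

#' Per-metabolite mean normalization
#'
#' Divides every metabolite by its own mean "across the time-point
#' measurements". By default the mean is taken over the monthly replicate
#' means (one value per month); `level = "replicate"` uses all individual
#' measurements instead (identical for balanced designs).
#'
#' @param x an [AbundanceTable-class] restricted to a single seed state, or
#'   a numeric matrix with variables in columns.
#' @param level `"month"` (default) or `"replicate"`.
#' @return object of the same class with every metabolite mean equal to 1.
#' @examples
#' meanNormalize(cbind(m = c(2, 4, 6)))
#' @export
meanNormalize <- function(x, level = c("month", "replicate")) {
  level <- match.arg(level)
  if (is(x, "AbundanceTable")) {
    mu <- if (level == "month") colMeans(monthlyMeans(x), na.rm = TRUE)
          else colMeans(abundanceValues(x), na.rm = TRUE)
    .checkMeans(mu)
    assay(x, "abundance") <- assay(x, "abundance") / mu
    return(x)
  }
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  .checkMeans(mu, colnames(x))
  sweep(x, 2, mu, `/`)
}

.checkMeans <- function(mu, nm = names(mu)) {
  bad <- which(is.na(mu) | mu == 0)
  if (length(bad)) {
    lab <- if (!is.null(nm)) nm[bad] else as.character(bad)
    stop("mean normalization undefined (zero or missing mean) for: ",
         paste(lab, collapse = ", "))
  }
}

#' Arcsine (angular) transformation of percentages
#'
#' The variance-stabilizing transform for percentage data:
#' `asin(sqrt(p / 100))`, in radians on `[0, pi/2]`. Strictly monotone on
#' `[0, 100]`.
#'
#' @param percentage numeric vector in `[0, 100]` (NA allowed).
#' @return transformed values in radians.
#' @examples
#' arcsinTransform(c(0, 50, 100))   # 0, pi/4, pi/2
#' @export
arcsinTransform <- function(percentage) {
  ok <- is.na(percentage) | (percentage >= 0 & percentage <= 100)
  if (!all(ok))
    stop("percentage out of [0, 100]: ",
         paste(utils::head(percentage[!ok], 3), collapse = ", "))
  asin(sqrt(percentage / 100))
}

#' Pareto scaling
#'
#' Column-wise mean centering followed by division by the square root of
#' the sample standard deviation: `(x - mean) / sqrt(sd)`. Compared with
#' unit-variance scaling this compresses large fold changes less; the
#' scaled column has mean 0 and variance equal to the original SD.
#'
#' @param x numeric matrix, variables in columns.
#' @return matrix of the same shape, columns mean-centered.
#' @examples
#' paretoScale(cbind(a = c(1, 2, 3)))   # -1, 0, 1
#' @export
paretoScale <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, sd, na.rm = TRUE)
  bad <- which(is.na(s) | s == 0)
  if (length(bad)) {
    lab <- if (!is.null(colnames(x))) colnames(x)[bad]
           else as.character(bad)
    stop("pareto scaling undefined (zero variance) for column(s): ",
         paste(lab, collapse = ", "))
  }
  sweep(sweep(x, 2, colMeans(x, na.rm = TRUE)), 2, sqrt(s), `/`)
}

#' Per-metabolite 0--1 scaling (heatmap scaling)
#'
#' Scales each variable to `[0, 1]` via `(x - min) / (max - min)`, the
#' convention used for abundance heatmaps. A constant variable is mapped
#' to 0.5 everywhere, with a warning.
#'
#' @param x numeric matrix, variables in columns.
#' @return matrix with each column in `[0, 1]`.
#' @examples
#' minmaxScale(cbind(a = c(2, 4, 6)))   # 0, 0.5, 1
#' @export
minmaxScale <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min, na.rm = TRUE)
  hi <- apply(x, 2, max, na.rm = TRUE)
  flat <- hi == lo
  if (any(flat)) {
    lab <- if (!is.null(colnames(x))) colnames(x)[flat]
           else as.character(which(flat))
    warning("constant variable(s) mapped to 0.5: ",
            paste(lab, collapse = ", "))
  }
  span <- ifelse(flat, 1, hi - lo)
  out <- sweep(sweep(x, 2, lo), 2, span, `/`)
  if (any(flat)) {
    sub <- out[, flat, drop = FALSE]
    sub[!is.na(sub)] <- 0.5
    out[, flat] <- sub
  }
  out
}

#' Fold change between two state means
#'
#' Ratio `meanA / meanB`; values above 1 indicate accumulation in
#' condition A relative to condition B.
#'
#' @param meanA,meanB positive means of the same metabolite under two
#'   conditions; `meanB` must be strictly positive.
#' @return `foldChange()`: the ratio.
#' @examples
#' foldChange(4.6, 0.2)   # 23
#' @export
foldChange <- function(meanA, meanB) {
  if (any(meanB == 0, na.rm = TRUE))
    stop("fold change undefined: reference mean is zero")
  meanA / meanB
}

#' @rdname foldChange
#' @param x an [AbundanceTable-class] containing both states.
#' @param stateA,stateB seed states to contrast (A relative to B).
#' @return `stateFoldChanges()`: data.frame with per-metabolite means in
#'   both states and their fold change, sorted by decreasing fold change.
#' @export
stateFoldChanges <- function(x, stateA, stateB) {
  mA <- colMeans(abundanceValues(subsetState(x, stateA)), na.rm = TRUE)
  mB <- colMeans(abundanceValues(subsetState(x, stateB)), na.rm = TRUE)
  fc <- foldChange(mA, mB)
  out <- data.frame(metabolite = names(mA), meanA = mA, meanB = mB,
                    foldChange = fc,
                    direction = ifelse(fc > 1, "accumulation", "depletion"),
                    row.names = NULL)
  out[order(-out$foldChange), ]
}
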