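## Exact permutation null distribution of Spearman's S = sum (rank diff)^2.
##
## For tie-free data of size n, S = 2*sum(i^2) - 2*T with T = sum i*pi(i)
## over a uniform random permutation pi. The distribution of T is computed
## exactly by a dynamic program over value subsets: positions are filled in
## order, state = set of ranks already used, so the k-th filled position
## contributes k*v for each unused rank v. Cost O(2^n * n * max(T)),
## practical for n <= 12 (12! = 479001600 paths collapsed into 4096 states).

.spearmanNullTable <- function(n) {
  key <- paste0("S", n)
  if (!is.null(.seasonetCache[[key]])) return(.seasonetCache[[key]])
  if (n > 12L) stop("exact Spearman null is computed for n <= 12 only")
  tmax <- sum((seq_len(n))^2)
  f <- vector("list", 2^n)
  f[[1]] <- c(1, numeric(tmax))
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  popcount <- function(mask) sum(bitwAnd(mask, bits) > 0L)
  for (mask in seq_len(2^n - 1L)) {
    k <- popcount(mask)                       # position being filled
    acc <- numeric(tmax + 1L)
    for (v in seq_len(n)) {
      bit <- bits[v]
      if (bitwAnd(mask, bit) > 0L) {
        sh <- k * v
        prev <- f[[mask - bit + 1L]]
        acc[(sh + 1L):(tmax + 1L)] <- acc[(sh + 1L):(tmax + 1L)] +
          prev[seq_len(tmax + 1L - sh)]
      }
    }
    f[[mask + 1L]] <- acc
    # free states no longer reachable to bound memory at small n; skipped
  }
  tdist <- f[[2^n]]
  svals <- 2 * tmax - 2 * (0:tmax)            # S for each T, descending
  keep <- tdist > 0
  S <- rev(svals[keep])
  count <- rev(tdist[keep])
  total <- sum(count)
  tab <- list(S = S,
              cumLE = cumsum(count) / total,
              cumGE = rev(cumsum(rev(count))) / total)
  .seasonetCache[[key]] <- tab
  tab
}

## Two-sided exact p-value for observed S (tie-free ranks), vectorized.
.spearmanExactP <- function(S, n) {
  tab <- .spearmanNullTable(n)
  S <- round(S)
  iLE <- findInterval(S, tab$S)               # last index with tab$S <= S
  pLE <- ifelse(iLE >= 1, tab$cumLE[pmax(iLE, 1)], 0)
  iGE <- findInterval(S - 0.5, tab$S) + 1     # first index with tab$S >= S
  pGE <- ifelse(iGE <= length(tab$S), tab$cumGE[pmin(iGE, length(tab$S))], 0)
  pmin(1, 2 * pmin(pLE, pGE))
}

## Two-sided t-approximation p-value from rho.
.spearmanTP <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho) & n >= 3
  r <- pmin(pmax(rho[ok], -1), 1)
  tt <- abs(r) * sqrt((n[ok] - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- pmin(1, 2 * pt(tt, n[ok] - 2, lower.tail = FALSE))
  p[ok][abs(r) == 1] <- 0
  p
}

## Full-enumeration permutation p-value for a single pair (n <= 9),
## tie-aware: rho compared against all n! permutations of y's ranks.
.spearmanPermutationP <- function(x, y) {
  n <- length(x)
  if (n > 9L) stop("full permutation enumeration supported for n <= 9 only")
  rx <- rank(x); ry <- rank(y)
  vx <- sum((rx - mean(rx))^2)
  vy <- sum((ry - mean(ry))^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  obs <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(vx * vy)
  perms <- .allPermutations(n)
  rperm <- matrix(ry[perms], nrow = nrow(perms))
  stat <- (rperm %*% (rx - mean(rx))) / sqrt(vx * vy)
  mean(abs(stat) >= abs(obs) - 1e-12)
}

.allPermutations <- function(n) {
  key <- paste0("P", n)
  if (!is.null(.seasonetCache[[key]])) return(.seasonetCache[[key]])
  res <- matrix(1L, 1, 1)
  if (n > 1) for (k in 2:n) {
    prev <- res
    m <- nrow(prev)
    res <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      res[rows, ] <- cbind(prev[, seq_len(pos - 1L), drop = FALSE],
                           k,
                           if (pos <= k - 1L)
                             prev[, pos:(k - 1L), drop = FALSE])
    }
  }
  .seasonetCache[[key]] <- res
  res
}
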