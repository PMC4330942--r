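test_that("Spearman rho equals the rank-then-Pearson oracle", {
  x <- c(1, 2, 3, 4); y <- c(10, 20, 30, 40)
  cs <- correlationMatrix(cbind(a = x, b = y), pMethod = "t")
  expect_equal(corRho(cs)["a", "b"], 1)
  cs <- correlationMatrix(cbind(a = x, b = rev(y)), pMethod = "t")
  expect_equal(corRho(cs)["a", "b"], -1)
  # worked tied example: rho = 1.5 / sqrt(2.5)
  cs <- correlationMatrix(cbind(a = c(1, 2, 2, 4), b = c(1, 3, 2, 4)),
                          pMethod = "t")
  expect_equal(corRho(cs)["a", "b"], 1.5 / sqrt(2.5), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    a <- sample(1:5, n, replace = TRUE) + runif(n) * (i %% 2)
    b <- sample(1:5, n, replace = TRUE) + runif(n) * (i %% 3 == 0)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    cs <- correlationMatrix(cbind(a = a, b = b), pMethod = "t")
    expect_equal(corRho(cs)["a", "b"], rankPearson(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- corRho(correlationMatrix(cbind(a = x, b = y)))["a", "b"]
  r1 <- corRho(correlationMatrix(cbind(a = exp(x), b = y)))["a", "b"]
  r2 <- corRho(correlationMatrix(cbind(a = x, b = atan(y) + 5)))["a", "b"]
  expect_equal(r0, r1)
  expect_equal(r0, r2)
})

test_that("exact permutation null matches cor.test at small n", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:9, 1)
    a <- rnorm(n); b <- rnorm(n)
    pRef <- suppressWarnings(
      cor.test(a, b, method = "spearman", exact = TRUE)$p.value)
    cs <- correlationMatrix(cbind(a = a, b = b), pMethod = "exact")
    expect_equal(corPval(cs)["a", "b"], pRef, tolerance = 1e-12)
    # full enumeration agrees too
    cs2 <- correlationMatrix(cbind(a = a, b = b), pMethod = "permutation")
    expect_equal(corPval(cs2)["a", "b"], pRef, tolerance = 1e-12)
  }
})

test_that("t-approximation p-values are computed from df = n - 2", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(12)
  cs <- correlationMatrix(cbind(a = x, b = y), pMethod = "t")
  r <- corRho(cs)["a", "b"]
  tt <- abs(r) * sqrt(10 / (1 - r^2))
  expect_equal(corPval(cs)["a", "b"], 2 * pt(tt, 10, lower.tail = FALSE))
})

test_that("constant variables are recorded as missing, not zero", {
  set.seed(8)
  x <- cbind(a = rnorm(12), flat = rep(2, 12), b = rnorm(12))
  expect_warning(cs <- correlationMatrix(x), "flat")
  expect_true(is.na(corRho(cs)["a", "flat"]))
  expect_false(is.na(corRho(cs)["a", "b"]))
})

test_that("pairwise-complete observations are used with missing data", {
  set.seed(9)
  x <- cbind(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  x[1:3, "c"] <- NA
  cs <- correlationMatrix(x)
  expect_equal(corNUsed(cs)["a", "c"], 9)
  expect_equal(corNUsed(cs)["a", "b"], 12)
  expect_equal(corRho(cs)["a", "c"],
               rankPearson(x[4:12, "a"], x[4:12, "c"]), tolerance = 1e-12)
})

test_that("BH threshold reproduces the hand computation", {
  expect_equal(pThresholdForQ(c(0.001, 0.01, 0.02, 0.2, 0.5), 0.05), 0.02)
  expect_equal(pThresholdForQ(rep(1, 10), 0.05), 0)
  expect_equal(pThresholdForQ(0.04, 0.05), 0.04)  # m = 1 reduces to p <= q
  expect_error(pThresholdForQ(numeric(0), 0.05), "no p-values")
  expect_error(pThresholdForQ(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("BH threshold agrees with the quadratic brute-force oracle", {
  set.seed(10)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_equal(pThresholdForQ(p, q), bruteBHThreshold(p, q))
  }
})

test_that("BH threshold is monotone nondecreasing in the target q", {
  set.seed(11)
  p <- runif(100)^2
  th <- vapply(seq(0.01, 0.2, by = 0.01),
               function(q) pThresholdForQ(p, q), 0)
  expect_true(all(diff(th) >= 0))
})

test_that("all pairs at or below the threshold have BH q <= target", {
  set.seed(12)
  x <- matrix(rnorm(12 * 15), 12, 15)
  x[, 2] <- x[, 1] + rnorm(12, sd = 0.1)   # plant one strong pair
  cs <- correlationMatrix(x)
  off <- upper.tri(corPval(cs))
  th <- pThresholdForQ(corPval(cs)[off], 0.05)
  sel <- corPval(cs)[off] <= th
  if (any(sel)) expect_true(all(corQval(cs)[off][sel] <= 0.05 + 1e-12))
})

test_that("normality screen flags heavy tails and spares normal data", {
  set.seed(13)
  heavy <- matrix(rcauchy(12 * 40), 12, 40)
  scH <- normalityScreen(heavy)
  expect_gt(scH$violationFraction, 0.5)
  expect_identical(scH$recommended, "spearman")
  # exact standard-normal quantiles are as normal as data can be
  qn <- matrix(rep(qnorm(ppoints(12)), 5), 12, 5)
  qn <- qn + matrix(rnorm(60, sd = 1e-6), 12, 5)  # break exact ties
  scN <- normalityScreen(qn)
  expect_equal(scN$violationFraction, 0)
  expect_identical(scN$recommended, "pearson")
  expect_error(normalityScreen(matrix(1:4, 2, 2)), ">= 3")
})

test_that("screen reports the violation fraction that drives the choice", {
  set.seed(14)
  x <- cbind(matrix(rcauchy(12 * 13), 12, 13),
             matrix(rep(qnorm(ppoints(12)), 1), 12, 1))
  sc <- normalityScreen(x)
  expect_equal(sc$violationFraction, mean(sc$table$violated))
  expect_identical(sc$recommended,
                   if (sc$violationFraction > 0.5) "spearman" else "pearson")
})

test_that("long-format correlation export is complete and symmetric-free", {
  set.seed(15)
  cs <- correlationMatrix(matrix(rnorm(48), 12, 4,
                                 dimnames = list(NULL, letters[1:4])))
  path <- withr::local_tempfile(fileext = ".csv")
  d <- writeCorrelations(cs, path)
  expect_equal(nrow(d), choose(4, 2))
  back <- read.csv(path)
  expect_equal(back$rho, d$rho)
})
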