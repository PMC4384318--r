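# Weighted-statistics core: hand-derived values and independent oracles.

test_that("weighted mean matches direct evaluation", {
  expect_equal(weightedMean(c(1, 2, 3), c(5, 5, 5)), 2)
  expect_equal(weightedMean(c(1, 3), c(1, 3)), 2.5)
  expect_equal(weightedMean(rep(4.2, 7), runif(7, 1, 10)), 4.2)
  expect_error(weightedMean(numeric(), numeric()), "empty")
  expect_error(weightedMean(c(1, 2), c(1, 0)), "positive")
})

test_that("weighted variance matches direct evaluation with W-1 denominator", {
  expect_equal(weightedVariance(rep(2, 5), c(1, 2, 3, 4, 5)), 0)
  expect_equal(weightedVariance(c(0, 1), c(1, 1)), 0.5)
  # scaling all weights by k changes the result by (W-1)/(kW-1) * k
  x <- c(-0.2, 0.1, 0.4, 0.9)
  w <- c(2, 3, 4, 1)
  k <- 10
  W <- sum(w)
  expect_equal(weightedVariance(x, k * w),
               weightedVariance(x, w) * k * (W - 1) / (k * W - 1))
  expect_error(weightedVariance(c(0, 1), c(0.4, 0.5)), "exceed 1")
})

test_that("effective sample size follows (sum w)^2 / sum w^2", {
  expect_equal(effectiveN(rep(3, 10)), 10)
  expect_equal(effectiveN(c(1, 1, 2)), 16 / 6)
  expect_equal(effectiveN(42), 1)
  expect_lte(effectiveN(runif(20, 1, 100)), 20)
})

test_that("standard error uses the t quantile at df = n* - 1", {
  expect_equal(standardError(0, 10), 0)
  # large n*: the t quantile approaches the normal 1.96
  expect_equal(standardError(1, 1e6, 0.05), qnorm(0.975) / 1000,
               tolerance = 1e-5)
  # against an independent quantile (root-finding on the integrated density)
  expect_equal(standardError(0.5, 10, 0.05),
               0.5 / sqrt(10) * tQuantile(0.975, 9), tolerance = 1e-8)
  # fractional df are honored
  expect_equal(standardError(1, 7.3, 0.1),
               tQuantile(0.95, 6.3) / sqrt(7.3), tolerance = 1e-8)
  expect_error(standardError(1, 1), "exceed 1")
})

test_that("the cluster t-test matches the printed statistic and df = n*", {
  # mu* = 0.5, sigma_w = 0.5, n* = 9 -> t = 3; via equal unit weights the
  # inputs are constructed so the weighted chain lands on those values
  x <- c(0.5 - 1, rep(0.5, 7), 0.5 + 1)
  w <- rep(1, 9)
  expect_equal(weightedMean(x, w), 0.5)
  expect_equal(sqrt(weightedVariance(x, w)), 0.5)
  ht <- testCluster(x, w)
  expect_equal(ht$tStat, 3)
  expect_equal(ht$pValue, 2 * tTailProb(-3, 9), tolerance = 1e-9)
  # null case
  ht0 <- testCluster(c(-1, 0, 1), c(2, 2, 2), mu0 = 0)
  expect_equal(ht0$tStat, 0)
  expect_equal(ht0$pValue, 1)
  # symmetry: negating x negates t, p unchanged
  htNeg <- testCluster(-x, w)
  expect_equal(htNeg$tStat, -ht$tStat)
  expect_equal(htNeg$pValue, ht$pValue)
})

test_that("zero-dispersion clusters follow the documented convention", {
  ht <- testCluster(rep(0.7, 5), rep(10, 5))
  expect_equal(ht$tStat, Inf)
  expect_equal(ht$pValue, 0)
  ht0 <- testCluster(rep(0, 5), rep(10, 5))
  expect_equal(ht0$tStat, 0)
  expect_equal(ht0$pValue, 1)
  # phi = 0 forces Q = 0 regardless of the clamped p
  expect_equal(suppressMessages(qualityScore(0, dispersionFactor(0, 0.7))), 0)
})

test_that("dispersion factor is sqrt(sd) times (1 + |mu*|)", {
  expect_equal(dispersionFactor(1, 0), 1)
  expect_equal(dispersionFactor(0.25, 1), 1)
  expect_equal(dispersionFactor(0.25, -1), 1)
  mus <- seq(0, 3, by = 0.25)
  expect_true(all(diff(dispersionFactor(0.4, mus)) > 0))
})

test_that("Q and P scores evaluate as printed", {
  expect_equal(qualityScore(1, 2.5), 0)
  expect_equal(qualityScore(0.1, 1), 10)
  expect_equal(qualityScore(1e-6, 0.8), 48)   # below the 50 threshold
  expect_error(qualityScore(1.5, 1), "exceed 1")
  # underflowing p is clamped to a finite Q, with a warning log
  expect_message(q <- qualityScore(0, 1), "clamped")
  expect_true(is.finite(q) && q > 3000)
  expect_equal(precisionScore(1), 0)
  expect_equal(precisionScore(exp(-3)), 30)
  expect_equal(precisionScore(exp(-2)), 20)
  expect_true(precisionScore(2) < 0)
  expect_true(is.na(precisionScore(0)))
})

test_that("copy-number estimates and bounds follow N_C * 2^(mu* +/- SE)", {
  est <- copyNumberEstimate(0, 0, 2)
  expect_equal(est, list(nSample = 2, nMin = 2, nMax = 2))
  expect_equal(copyNumberEstimate(1, 0.1, 2)$nSample, 4)
  expect_equal(copyNumberEstimate(-1, 0.1, 2)$nSample, 1)
  est2 <- copyNumberEstimate(0.3, 0.2, 2)
  expect_true(est2$nMin <= est2$nSample && est2$nSample <= est2$nMax)
  expect_equal(est2$nMin, 2 * 2^0.1)
  expect_equal(est2$nMax, 2 * 2^0.5)
  expect_error(copyNumberEstimate(0, 0.1, 0), ">= 1")
})

test_that("sample/control swap antisymmetry propagates through the chain", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    x <- rnorm(n, 0.3, 0.4)
    w <- runif(n, 100, 3000)
    a <- testCluster(x, w)
    b <- testCluster(-x, w)
    expect_equal(b$muStar, -a$muStar)
    expect_equal(b$tStat, -a$tStat)
    expect_equal(b$pValue, a$pValue)
    expect_equal(b$sigmaW2, a$sigmaW2)
    expect_equal(b$nStar, a$nStar)
    # N_S -> N_C^2 / N_S under the swap (shared N_C)
    expect_equal(copyNumberEstimate(b$muStar, 0, 2)$nSample,
                 4 / copyNumberEstimate(a$muStar, 0, 2)$nSample)
    # Q monotone decreasing in p at fixed phi
    phi <- dispersionFactor(sqrt(a$sigmaW2), a$muStar)
    ps <- sort(runif(5, 1e-12, 1))
    expect_true(all(diff(qualityScore(ps, phi)) < 0))
  }
})
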