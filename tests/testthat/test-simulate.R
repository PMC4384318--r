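test_that("simulation is reproducible from the seed and leaves the RNG alone", {
  panel <- makePanel(5, 10)
  set.seed(123); before <- rnorm(1)
  a <- simulateComparison(panel, seed = 42)
  b <- simulateComparison(panel, seed = 42)
  expect_identical(a, b)
  c <- simulateComparison(panel, seed = 43)
  expect_false(identical(a$sample$count, c$sample$count))
  set.seed(123)
  expect_identical(rnorm(1), before)
})

test_that("panel layout matches the requested geometry", {
  panel <- makePanel(40, 40)
  expect_equal(nrow(panel), 40L)
  sim <- simulateComparison(panel, seed = 1)
  expect_equal(nrow(sim$sample), 1600L)
  expect_equal(nrow(sim$control), 1600L)
  # clusters on the same chromosome sit >= 2 Mbp apart
  byChrom <- split(panel$start, panel$chrom)
  gaps <- unlist(lapply(byChrom, function(s) diff(sort(s))))
  if (length(gaps)) expect_true(all(gaps >= 2e6))
})

test_that("an all-diploid panel has near-zero median log2 ratio", {
  panel <- makePanel(40, 40)
  sim <- simulateComparison(panel, outlierRate = 0, seed = 314)
  r <- log2(sim$sample$count / sim$control$count)
  expect_lt(abs(median(r)), 0.05)
})

test_that("a planted 2->4 cluster centres near x = 1 after normalization", {
  panel <- makePanel(20, 40)
  truth <- data.frame(cluster = "sim010", nControl = 2L, nSample = 4L)
  sim <- simulateComparison(panel, truth = truth, outlierRate = 0,
                            seed = 11)
  cmp <- normalizeCounts(pairCounts(sim$sample, sim$control))
  x <- log2Ratios(cmp)
  inCluster <- sim$sample$gene == "GENE010"
  expect_equal(mean(x[inCluster]), 1, tolerance = 0.1)
  expect_lt(abs(mean(x[!inCluster])), 0.05)
})

test_that("the truth table records planted events", {
  panel <- makePanel(6, 12)
  truth <- data.frame(cluster = "sim005", nControl = 2L, nSample = 1L)
  sim <- simulateComparison(panel, truth = truth, seed = 9)
  expect_equal(sum(sim$truth$nSample < sim$truth$nControl), 1L)
  expect_equal(sim$truth$cluster[sim$truth$nSample == 1L], "sim005")
  expect_error(simulateComparison(panel,
                                  truth = data.frame(cluster = "nope",
                                                     nControl = 2,
                                                     nSample = 4),
                                  seed = 1),
               "unknown cluster")
})

test_that("evaluateCalls applies the direction-agreement counting rule", {
  panel <- makePanel(5, 15)
  truth <- data.frame(cluster = c("sim002", "sim004"), nControl = 2L,
                      nSample = c(4L, 1L))
  sim <- simulateComparison(panel, truth = truth, seed = 8)
  calls <- callCnv(sim$sample, sim$control)
  ev <- evaluateCalls(calls, sim$truth)
  expect_equal(ev$tp + ev$tn + ev$fp + ev$fn, 5)
  expect_equal(ev$tp, 2); expect_equal(ev$tn, 3)
  expect_equal(ev$tpr, 1); expect_equal(ev$tnr, 1)

  # flip a correct gain call into a loss: the disagreeing positive call
  # counts as FP, not TP
  flipped <- calls
  mc <- GenomicRanges::mcols(flipped@calls)
  i <- which(mc$status == "gain")
  mc$status[i] <- "loss"
  GenomicRanges::mcols(flipped@calls) <- mc
  ev2 <- evaluateCalls(flipped, sim$truth)
  expect_equal(ev2$fp, 1)
  expect_equal(ev2$tp, 1)

  # truth missing for a cluster is an error
  expect_error(evaluateCalls(calls, sim$truth[-1, ]), "no truth entry")
})

test_that("evaluateCalls reports NA rates for degenerate truth", {
  panel <- makePanel(4, 15)
  sim <- simulateComparison(panel, seed = 6)
  calls <- callCnv(sim$sample, sim$control)
  ev <- evaluateCalls(calls, sim$truth)   # no true CNVs anywhere
  expect_true(is.na(ev$tpr))
  expect_equal(ev$tnr, 1)
})

test_that("very precise calls (P > 30) estimate copy number within 10 percent", {
  # P > 30 means SE < e^-3; that regime needs larger clusters and deeper
  # coverage than the standard benchmark, so probe it at 100 amplicons
  # per cluster and depth 2000
  panel <- makePanel(20, 100)
  truth <- data.frame(cluster = panel$cluster[seq(2, 18, by = 4)],
                      nControl = 2L, nSample = c(3L, 1L, 3L, 1L, 3L))
  per <- NULL
  for (s in 1:4) {
    sim <- simulateComparison(panel, truth = truth, depth = 2000,
                              seed = 100 + s)
    res <- evaluateCalls(callCnv(sim$sample, sim$control), sim$truth)
    per <- rbind(per, res$perCluster)
  }
  ok <- per$status != "uncallable" & !is.na(per$pScore) & per$pScore > 30
  expect_gt(sum(ok), 20)
  relErr <- abs(per$copyNumber[ok] - per$trueSample[ok]) / per$trueSample[ok]
  expect_gte(mean(relErr < 0.10), 0.80)
})

test_that("copy-number estimates are unbiased across CN 1 to 4", {
  panel <- makePanel(40, 40)
  slots <- seq(2, 30, by = 4)
  truth <- data.frame(cluster = panel$cluster[slots], nControl = 2L,
                      nSample = c(1L, 3L, 4L, 1L, 3L, 4L, 1L, 3L))
  cn <- NULL
  for (s in 1:6) {
    sim <- simulateComparison(panel, truth = truth, seed = 200 + s)
    res <- evaluateCalls(callCnv(sim$sample, sim$control), sim$truth)
    cn <- rbind(cn, res$perCluster[c("copyNumber", "trueSample")])
  }
  means <- tapply(cn$copyNumber, cn$trueSample, mean)
  expect_true(all(abs(means - as.numeric(names(means))) < 0.15))
})

test_that("ROC staircase has the documented anchors and symmetries", {
  # perfect separation -> area 1
  expect_equal(rocArea(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)), 1)
  # reversing the score sign maps area a -> 1 - a
  set.seed(21)
  sc <- runif(40)
  lb <- rep(c(TRUE, FALSE), 20)
  expect_equal(rocArea(-sc, lb), 1 - rocArea(sc, lb))
  pts <- rocPoints(sc, lb)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # random scores on balanced labels -> area near 1/2 over seeds
  set.seed(22)
  areas <- replicate(40, rocArea(runif(60), rep(c(TRUE, FALSE), 30)))
  expect_lt(abs(mean(areas) - 0.5), 0.05)
  expect_error(rocPoints(1:3, c(TRUE, TRUE, TRUE)), "negative")
})
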