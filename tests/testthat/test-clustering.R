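# Positional clustering fixtures: each branch of the gap-splitting rules,
# with the expected partitions worked out by hand from the rule set.

clusterOf <- function(cmp) clusterIds(cmp)

test_that("a >250 kbp gap splits a small cluster into two halves of 10", {
  # 20 amplicons, one internal gap of 300,001 bp, all other gaps 1 kbp:
  # cluster has <100 members so the >=100 kbp small-cluster rule also holds
  pos <- c(seq(1e5, by = 1000, length.out = 10),
           seq(1e5 + 9000 + 300001, by = 1000, length.out = 10))
  cmp <- assignClusters(makeComparison("chr1", pos, 100, 100))
  cl <- clusterOf(cmp)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(as.integer(table(cl)[unique(cl)]), c(10L, 10L))
})

test_that("a 50 kbp gap never splits a small cluster", {
  # 15 amplicons, largest gap 50 kbp: both halves would hold >= 10 fails
  # anyway on one side, and 50 kbp < 100 kbp blocks any small-cluster split
  pos <- c(seq(1e5, by = 500, length.out = 8),
           seq(1e5 + 3500 + 50000, by = 500, length.out = 7))
  cmp <- assignClusters(makeComparison("chr2", pos, 100, 100))
  expect_equal(length(unique(clusterOf(cmp))), 1L)
})

test_that("a 100-150 kbp gap splits a small cluster only with 10 a side", {
  # 24 amplicons, gap of 120 kbp at 12|12: qualifies (>=10 both sides,
  # >=100 kbp)
  pos <- c(seq(1e5, by = 500, length.out = 12),
           seq(1e5 + 5500 + 120000, by = 500, length.out = 12))
  cmp <- assignClusters(makeComparison("chr3", pos, 100, 100))
  expect_equal(length(unique(clusterOf(cmp))), 2L)
  # same gap at 4|20 does not qualify (<10 members on one side, gap
  # not > 250 kbp)
  pos2 <- c(seq(1e5, by = 500, length.out = 4),
            seq(1e5 + 1500 + 120000, by = 500, length.out = 20))
  cmp2 <- assignClusters(makeComparison("chr3", pos2, 100, 100))
  expect_equal(length(unique(clusterOf(cmp2))), 1L)
})

test_that("large clusters split at sub-100 kbp gaps when 10 a side remain", {
  # 120 amplicons with a 60 kbp gap at 60|60: cluster is >= 100 members,
  # so the small-cluster gap rule does not apply and the 10-a-side branch
  # fires
  pos <- c(seq(1e5, by = 200, length.out = 60),
           seq(1e5 + 59 * 200 + 60000, by = 200, length.out = 60))
  cmp <- assignClusters(makeComparison("chr4", pos, 100, 100))
  expect_equal(length(unique(clusterOf(cmp))), 2L)
})

test_that("splitting recurses: three widely separated groups emerge", {
  pos <- c(seq(1e5, by = 500, length.out = 12),
           seq(2e6, by = 500, length.out = 12),
           seq(4e6, by = 500, length.out = 12))
  cmp <- assignClusters(makeComparison("chr5", pos, 100, 100))
  cl <- clusterOf(cmp)
  expect_equal(length(unique(cl)), 3L)
  expect_equal(as.integer(table(cl)[unique(cl)]), c(12L, 12L, 12L))
})

test_that("chromosomes initialize one cluster each", {
  s <- countTable(rep(c("chr1", "chr2", "chr3"), each = 5),
                  rep(1:5 * 100, 3), 100)
  cmp <- assignClusters(pairCounts(s, s))
  expect_equal(length(unique(clusterOf(cmp))), 3L)
})

test_that("clusters partition the primers and no boundary violates the rules", {
  set.seed(303)
  pos <- sort(sample(1:5e6, 400))
  cmp <- assignClusters(makeComparison("chr6", pos, 100, 100))
  cl <- clusterOf(cmp)
  expect_false(anyNA(cl))                      # cover all primers
  # idempotence: re-clustering any single produced cluster leaves it whole
  # unless it still contains a qualifying gap (it must not)
  for (id in unique(cl)) {
    sub <- pos[cl == id]
    subCmp <- assignClusters(makeComparison("chr6", sub, 100, 100))
    expect_equal(length(unique(clusterIds(subCmp))), 1L)
  }
})

test_that("gene-annotation mode groups by (chrom, gene)", {
  s <- countTable(rep("chr7", 20), 1:20 * 100, 100,
                  gene = rep(c("EGFR", "MET"), each = 10))
  cmp <- assignClustersByGene(pairCounts(s, s))
  cl <- clusterIds(cmp)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(as.integer(table(cl)[unique(cl)]), c(10L, 10L))
  # same gene label on two chromosomes -> two clusters
  s2 <- countTable(rep(c("chr1", "chr2"), each = 5), rep(1:5 * 10, 2), 50,
                   gene = "DUPGENE")
  expect_equal(length(unique(clusterIds(assignClustersByGene(pairCounts(s2, s2))))),
               2L)
  # one gene -> one cluster spanning the table
  s3 <- countTable("chr3", 1:8 * 10, 50, gene = "ONE")
  expect_equal(length(unique(clusterIds(assignClustersByGene(pairCounts(s3, s3))))),
               1L)
})

test_that("gene mode requires a label on every primer", {
  s <- countTable("chr7", 1:10 * 100, 100,
                  gene = c(rep("EGFR", 9), NA))
  expect_error(assignClustersByGene(pairCounts(s, s)), "gene")
})

test_that("cluster BED export is 0-based half-open", {
  pos <- c(seq(1e5, by = 1000, length.out = 10),
           seq(5e6, by = 1000, length.out = 10))
  cmp <- assignClusters(makeComparison("chr8", pos, 100, 100))
  path <- withr::local_tempfile(fileext = ".bed")
  exportClusterBed(cmp, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$V2, c(1e5 - 1, 5e6 - 1))
  expect_equal(bed$V3, c(1e5 + 9000, 5e6 + 9000))
})
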