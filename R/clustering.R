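# Positional clustering of primers: the calling unit is a cluster of
# amplicons assumed to share one copy-number state (no intra-cluster
# segmentation). Starting from one cluster per chromosome, clusters are
# recursively split at the largest qualifying gap between adjacent primer
# 5' positions until no gap qualifies.

# Index of the gap to split at, or 0L. pos must be sorted. A gap after
# element g qualifies when (both halves have >= minSplit members OR the
# gap exceeds gapLarge) AND (the cluster has >= smallCluster members OR
# the gap is at least gapSmall). Gaps are visited largest-first
# (leftmost on ties) and the first qualifying one wins.
.splitPoint <- function(pos, minSplit, gapLarge, gapSmall, smallCluster) {
  n <- length(pos)
  if (n < 2) return(0L)
  gaps <- diff(pos)
  for (g in order(-gaps, seq_along(gaps))) {
    gap <- gaps[g]
    sizeOk <- (g >= minSplit && (n - g) >= minSplit) || gap > gapLarge
    smallOk <- n >= smallCluster || gap >= gapSmall
    if (sizeOk && smallOk) return(g)
  }
  0L
}

.partitionPositions <- function(pos, minSplit, gapLarge, gapSmall,
                                smallCluster) {
  n <- length(pos)
  rec <- function(lo, hi) {
    g <- .splitPoint(pos[lo:hi], minSplit, gapLarge, gapSmall, smallCluster)
    if (g == 0L) return(list(c(lo, hi)))
    c(rec(lo, lo + g - 1L), rec(lo + g, hi))
  }
  rec(1L, n)
}

#' Group primers into positional clusters
#'
#' Assigns every primer of a normalized comparison to a cluster, the unit
#' of copy-number calling. Per chromosome, all primers start in one
#' cluster; the largest gap between adjacent primer positions is then used
#' to split recursively. A split is made when both resulting clusters would
#' keep at least \code{minSplit} primers \emph{or} the gap exceeds
#' \code{gapLarge}; clusters with fewer than \code{smallCluster} primers
#' are additionally only ever split at gaps of at least \code{gapSmall}.
#' Recursion stops when no gap qualifies. Defaults (10 members, 250 kbp,
#' 100 kbp, 100 members) balance granularity against per-cluster power:
#' large genes with distant exons split into several clusters while
#' neighboring small genes merge into one.
#'
#' @param comparison An \code{\link{AmpliconComparison}}.
#' @param minSplit Minimum members on both sides of an ordinary split.
#' @param gapLarge Gap (bp) above which a split is always allowed
#'   (strictly greater).
#' @param gapSmall Minimum gap (bp) required to split a cluster smaller
#'   than \code{smallCluster} (at least).
#' @param smallCluster Cluster size below which the \code{gapSmall} rule
#'   applies.
#' @return The comparison with the \code{cluster} metadata column filled
#'   with labels of the form \code{"chr7:c1"}, numbered by position within
#'   each chromosome.
#' @export
assignClusters <- function(comparison, minSplit = 10L, gapLarge = 250000L,
                           gapSmall = 100000L, smallCluster = 100L) {
  stopifnot(methods::is(comparison, "AmpliconComparison"))
  gr <- comparison@sites
  if (!length(gr)) stop("cannot cluster an empty comparison")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  cl <- character(length(gr))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)           # already sorted by pos
    parts <- .partitionPositions(pos[i], minSplit, gapLarge, gapSmall,
                                 smallCluster)
    for (k in seq_along(parts)) {
      lohi <- parts[[k]]
      cl[i[lohi[1]:lohi[2]]] <- sprintf("%s:c%d", ch, k)
    }
  }
  GenomicRanges::mcols(comparison@sites)$cluster <- cl
  comparison
}

#' Group primers by gene annotation instead of position
#'
#' Gene-annotation ("no-cluster") mode: one cluster per distinct
#' \code{(chrom, gene)} label, used to match target regions defined by a
#' gene panel rather than by positional gaps. Every primer must carry a
#' gene label.
#'
#' @param comparison An \code{\link{AmpliconComparison}} whose primers all
#'   have a \code{gene} annotation.
#' @return The comparison with \code{cluster} set to
#'   \code{"<chrom>:<gene>"}.
#' @export
assignClustersByGene <- function(comparison) {
  stopifnot(methods::is(comparison, "AmpliconComparison"))
  mc <- GenomicRanges::mcols(comparison@sites)
  if (any(is.na(mc$gene)) || any(!nzchar(mc$gene)))
    stop("gene-annotation clustering requires a gene label on every primer ",
         "(missing 'gene' column entries)")
  chrom <- as.character(GenomicRanges::seqnames(comparison@sites))
  GenomicRanges::mcols(comparison@sites)$cluster <-
    paste0(chrom, ":", mc$gene)
  comparison
}

# Cluster spans (1-based inclusive) of an assigned comparison, ordered by
# (chrom, span start).
.clusterTable <- function(comparison) {
  cl <- GenomicRanges::mcols(comparison@sites)$cluster
  if (is.null(cl) || anyNA(cl))
    stop("clusters not assigned; run assignClusters() or ",
         "assignClustersByGene() first")
  chrom <- as.character(GenomicRanges::seqnames(comparison@sites))
  pos <- GenomicRanges::start(comparison@sites)
  idx <- split(seq_along(cl), cl)
  df <- data.frame(
    cluster = names(idx),
    chrom = vapply(idx, function(i) chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(pos[i]), numeric(1)),
    end = vapply(idx, function(i) max(pos[i]), numeric(1)),
    n = lengths(idx),
    stringsAsFactors = FALSE
  )
  o <- order(match(df$chrom, .orderedSeqlevels(df$chrom)), df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "indices") <- idx[df$cluster]
  df
}

#' Export cluster definitions as BED
#'
#' Writes one BED line per cluster (0-based half-open per BED convention)
#' for inspection in a genome browser.
#'
#' @param comparison An \code{\link{AmpliconComparison}} with clusters
#'   assigned.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportClusterBed <- function(comparison, path) {
  tab <- .clusterTable(comparison)
  writeLines(sprintf("%s\t%d\t%d\t%s", tab$chrom, as.integer(tab$start) - 1L,
                     as.integer(tab$end), tab$cluster), path)
  invisible(path)
}
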