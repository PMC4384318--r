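# Evaluation of calls against simulated truth: confusion counts with the
# direction-agreement rule, and a minimal ROC implementation.

#' Score calls against a truth table
#'
#' Each call-set cluster is matched to the truth cluster its span
#' overlaps. A cluster is a \emph{positive} call iff it passed the Q
#' threshold; it counts as a true positive when its direction (gain or
#' loss) agrees with the planted change — an exact copy-number match is
#' not required, but a passing call in the \emph{wrong} direction on a
#' changed cluster is a false positive. Non-passing (including
#' uncallable) clusters are negatives: true negatives on unchanged
#' clusters, false negatives on changed ones.
#'
#' @param callSet A \code{\link{CnvCallSet}}.
#' @param truth Truth \code{data.frame} from
#'   \code{\link{simulateComparison}} (needs \code{chrom}, \code{start},
#'   \code{end}, \code{nControl}, \code{nSample}).
#' @return A list with \code{tp}, \code{tn}, \code{fp}, \code{fn},
#'   \code{tpr} (NA when there are no true changes), \code{tnr} (NA when
#'   all clusters are changed), and \code{perCluster}, a
#'   \code{data.frame} joining every call to its truth.
#' @export
evaluateCalls <- function(callSet, truth) {
  stopifnot(methods::is(callSet, "CnvCallSet"))
  gr <- callSet@calls
  mc <- GenomicRanges::mcols(gr)
  trGr <- GenomicRanges::GRanges(
    seqnames = factor(truth$chrom,
                      levels = union(GenomeInfoDb::seqlevels(gr),
                                     unique(truth$chrom))),
    ranges = IRanges::IRanges(start = truth$start, end = truth$end))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(trGr)
  ov <- GenomicRanges::findOverlaps(gr, trGr)
  hit <- S4Vectors::queryHits(ov)
  if (anyDuplicated(hit))
    stop("a call cluster overlaps more than one truth cluster")
  if (length(unique(hit)) < length(gr)) {
    miss <- setdiff(seq_along(gr), hit)[1]
    stop(sprintf("no truth entry for cluster %s", mc$clusterId[miss]))
  }
  tIdx <- S4Vectors::subjectHits(ov)[order(hit)]

  trueDir <- sign(truth$nSample[tIdx] - truth$nControl[tIdx])
  changed <- trueDir != 0
  positive <- mc$passed
  callDir <- ifelse(mc$status == "gain", 1L,
                    ifelse(mc$status == "loss", -1L, 0L))
  tp <- sum(positive & changed & callDir == trueDir)
  fp <- sum(positive & (callDir != trueDir))
  tn <- sum(!positive & !changed)
  fn <- sum(!positive & changed)
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    perCluster = data.frame(
      clusterId = mc$clusterId, status = mc$status, passed = mc$passed,
      qScore = mc$qScore, pScore = mc$pScore, pValue = mc$pValue,
      muStar = mc$muStar, copyNumber = mc$copyNumber,
      trueControl = truth$nControl[tIdx],
      trueSample = truth$nSample[tIdx],
      stringsAsFactors = FALSE)
  )
}

#' ROC staircase over score thresholds
#'
#' Sweeps the decision threshold over the sorted unique scores and
#' returns the (FPR, TPR) staircase, anchored at (0,0) and (1,1). A
#' cluster is predicted positive when its score is at or above the
#' threshold.
#'
#' @param scores Numeric scores (e.g. Q); higher = more confident
#'   positive.
#' @param labels Logical (or 0/1) truth: TRUE = changed cluster.
#' @return A \code{data.frame} with columns \code{threshold} (NA for the
#'   two anchors), \code{fpr}, \code{tpr}.
#' @export
rocPoints <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("ROC requires at least one positive and one negative label")
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nNeg,
                numeric(1))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / nPos,
                numeric(1))
  data.frame(threshold = c(NA, thr, NA), fpr = c(0, fpr, 1),
             tpr = c(0, tpr, 1))
}

#' Area under the ROC staircase
#'
#' Trapezoidal area under \code{\link{rocPoints}}; ties in the scores are
#' handled by the trapezoids.
#'
#' @param scores,labels As in \code{\link{rocPoints}}.
#' @return The AUC in [0, 1].
#' @export
rocArea <- function(scores, labels) {
  pts <- rocPoints(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Operating characteristics on replicated simulated panels
#'
#' Simulates \code{nPanels} independent panels with planted single-copy
#' events, runs the full caller on each, and pools the confusion counts.
#' Events are planted on every fourth cluster (slots 2, 6, 10, ...),
#' alternating gain (2 to 3) and loss (2 to 1), so the panel stays
#' balanced and the median-normalization assumption (fewer than half the
#' primers affected) holds. Panel \code{i} uses seed \code{seed + i - 1}.
#'
#' @param nPanels Number of replicate panels.
#' @param clustersPerPanel,ampliconsPerCluster Panel geometry.
#' @param depth,efficiencySd,dispersion,outlierRate Passed to
#'   \code{\link{simulateComparison}}.
#' @param config A \code{\link{callerConfig}}.
#' @param seed Base seed.
#' @return A list: \code{sensitivity}, \code{specificity}, pooled
#'   \code{tp}/\code{tn}/\code{fp}/\code{fn}, \code{nClusters},
#'   \code{nEvents}, and \code{perCluster} (the pooled per-cluster table
#'   from \code{\link{evaluateCalls}} plus a \code{panel} column).
#' @export
benchmarkCaller <- function(nPanels = 24L, clustersPerPanel = 40L,
                            ampliconsPerCluster = 40L, depth = 1000,
                            efficiencySd = 0.15, dispersion = 80,
                            outlierRate = 0.02, config = callerConfig(),
                            seed = 1L) {
  panel <- makePanel(clustersPerPanel, ampliconsPerCluster)
  ev <- seq(2L, clustersPerPanel, by = 4L)
  truth <- data.frame(
    cluster = panel$cluster[ev],
    nControl = 2L,
    nSample = ifelse(seq_along(ev) %% 2 == 1, 3L, 1L))
  per <- vector("list", nPanels)
  agg <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_len(nPanels)) {
    sim <- simulateComparison(panel, truth = truth, depth = depth,
                              efficiencySd = efficiencySd,
                              dispersion = dispersion,
                              outlierRate = outlierRate,
                              seed = seed + i - 1L)
    calls <- callCnv(sim$sample, sim$control, config = config)
    res <- evaluateCalls(calls, sim$truth)
    agg <- agg + c(tp = res$tp, tn = res$tn, fp = res$fp, fn = res$fn)
    per[[i]] <- cbind(panel = i, res$perCluster)
  }
  perCluster <- do.call(rbind, per)
  list(sensitivity = unname(agg["tp"] / (agg["tp"] + agg["fn"])),
       specificity = unname(agg["tn"] / (agg["tn"] + agg["fp"])),
       tp = unname(agg["tp"]), tn = unname(agg["tn"]),
       fp = unname(agg["fp"]), fn = unname(agg["fn"]),
       nClusters = nrow(perCluster), nEvents = nPanels * length(ev),
       perCluster = perCluster)
}

#' Smallest achievable FPR + FNR over all thresholds
#'
#' Convenience for threshold-free comparison of two scorings of the same
#' truth (e.g. Q versus the uncorrected Phred-scaled p-value): the
#' minimum over the ROC staircase of FPR + (1 - TPR).
#'
#' @param scores,labels As in \code{\link{rocPoints}}.
#' @return The minimal error sum in [0, 1].
#' @export
minErrorSum <- function(scores, labels) {
  pts <- rocPoints(scores, labels)
  min(pts$fpr + 1 - pts$tpr)
}
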