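#' Caller configuration
#'
#' Bundles every tunable of the calling pipeline with its default:
#' \code{qThreshold} = 50 (Phred-like Q score at or above which a cluster
#' is called), \code{alpha} = 0.05 (confidence level for the copy-number
#' bounds), \code{swAlpha} = 0.05 (Shapiro-Wilk rejection level for
#' outlier pruning), \code{minCluster} = 10 (minimum usable primers for a
#' callable cluster), and the positional-clustering thresholds
#' (\code{gapLarge} = 250 kbp, \code{gapSmall} = 100 kbp,
#' \code{smallCluster} = 100, \code{minSplit} = 10).
#'
#' @param qThreshold,alpha,swAlpha,minCluster,gapLarge,gapSmall,
#'   smallCluster,minSplit See above.
#' @param noCluster Use gene-annotation clustering
#'   (\code{\link{assignClustersByGene}}) instead of positional gaps.
#' @param emitNoChange Emit no_change/uncallable clusters in the VCF
#'   (default TRUE, for auditability).
#' @return A named list of class \code{"CallerConfig"}.
#' @export
callerConfig <- function(qThreshold = 50, alpha = 0.05, swAlpha = 0.05,
                         minCluster = 10L, gapLarge = 250000L,
                         gapSmall = 100000L, smallCluster = 100L,
                         minSplit = 10L, noCluster = FALSE,
                         emitNoChange = TRUE) {
  stopifnot(qThreshold > 0, alpha > 0, alpha < 1, swAlpha > 0, swAlpha < 1,
            minCluster > 0, gapLarge > 0, gapSmall > 0, smallCluster > 0,
            minSplit > 0)
  structure(list(qThreshold = qThreshold, alpha = alpha, swAlpha = swAlpha,
                 minCluster = as.integer(minCluster),
                 gapLarge = as.integer(gapLarge),
                 gapSmall = as.integer(gapSmall),
                 smallCluster = as.integer(smallCluster),
                 minSplit = as.integer(minSplit),
                 noCluster = isTRUE(noCluster),
                 emitNoChange = isTRUE(emitNoChange)),
            class = "CallerConfig")
}

#' Control copy number of a chromosome
#'
#' Autosomes carry 2 copies in a diploid control; chrX and chrY depend on
#' the control's sex. chrY in a female control has 0 copies, which makes
#' any cluster there uncallable; unknown sex makes chrX/chrY uncallable
#' (NA) rather than guessing.
#'
#' @param chrom Chromosome name (with or without "chr" prefix).
#' @param controlSex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @return Integer copy number, or NA when the sex is required but
#'   unknown.
#' @export
controlCopies <- function(chrom, controlSex = "unknown") {
  key <- .chromKey(chrom)
  if (key == "X") {
    switch(controlSex, female = 2L, male = 1L, NA_integer_)
  } else if (key == "Y") {
    switch(controlSex, female = 0L, male = 1L, NA_integer_)
  } else 2L
}

# One row of per-cluster results, all fields present (NA where not
# computed). Degenerate clusters become status "uncallable" with a reason
# instead of erroring.
.callOne <- function(x, w, chrom, config, controlSex) {
  out <- list(nPrimers = length(x), nKept = NA_integer_,
              nControl = NA_integer_, copyNumber = NA_real_,
              cnMin = NA_real_, cnMax = NA_real_, muStar = NA_real_,
              sigmaW2 = NA_real_, nStar = NA_real_, se = NA_real_,
              tStat = NA_real_, pValue = NA_real_, phi = NA_real_,
              qScore = NA_real_, pScore = NA_real_, status = "uncallable",
              passed = FALSE, reason = "")
  uncallable <- function(reason) { out$reason <- reason; out }

  ok <- w > 0
  if (any(!ok)) {
    x <- x[ok]; w <- w[ok]
  }
  if (length(x) < 3)
    return(uncallable("fewer_than_3_primers"))

  pruned <- removeOutliers(x, w, swAlpha = config$swAlpha)
  xk <- x[pruned$keep]
  wk <- w[pruned$keep]
  out$nKept <- length(xk)
  flags <- character()
  if (pruned$capHit) flags <- c(flags, "outlier_cap_hit")
  if (out$nKept < config$minCluster)
    return(uncallable(paste(c("fewer_than_min_usable_primers", flags),
                            collapse = ";")))

  nC <- controlCopies(chrom, controlSex)
  if (is.na(nC)) return(uncallable("sex_unknown_for_allosome"))
  if (nC == 0L) return(uncallable("zero_control_copies"))
  out$nControl <- nC

  ht <- testCluster(xk, wk, mu0 = 0)
  if (ht$nStar <= 1)
    return(uncallable(paste(c("degenerate_effective_sample_size", flags),
                            collapse = ";")))
  sigmaW <- sqrt(ht$sigmaW2)
  se <- if (sigmaW == 0) 0 else standardError(sigmaW, ht$nStar, config$alpha)
  phi <- dispersionFactor(sigmaW, ht$muStar)
  q <- qualityScore(max(ht$pValue, 0), phi)
  if (sigmaW == 0) flags <- c(flags, "zero_dispersion")
  est <- copyNumberEstimate(ht$muStar, se, nC)

  out$muStar <- ht$muStar
  out$sigmaW2 <- ht$sigmaW2
  out$nStar <- ht$nStar
  out$se <- se
  out$tStat <- ht$tStat
  out$pValue <- ht$pValue
  out$phi <- phi
  out$qScore <- q
  out$pScore <- precisionScore(se)
  out$copyNumber <- est$nSample
  out$cnMin <- est$nMin
  out$cnMax <- est$nMax
  out$passed <- q >= config$qThreshold
  out$status <- if (out$passed) {
    if (est$nSample > nC) "gain" else "loss"
  } else "no_change"
  out$reason <- paste(flags, collapse = ";")
  out
}

#' Call one cluster
#'
#' Runs outlier pruning, the weighted statistics chain and the Q-score
#' threshold on a single cluster of normalized log2 ratios. Used by
#' \code{\link{callCnv}}; exposed for inspection of individual clusters.
#'
#' @param x Normalized log2 ratios of the cluster's primers (genomic
#'   order).
#' @param w Matching positive weights (summed sample+control counts).
#' @param chrom Chromosome of the cluster.
#' @param config A \code{\link{callerConfig}}.
#' @param controlSex Sex of the control, for chrX/chrY.
#' @return A named list of per-cluster results (see
#'   \code{\link{CnvCallSet}} column descriptions).
#' @export
callCluster <- function(x, w, chrom, config = callerConfig(),
                        controlSex = "unknown") {
  .callOne(x, w, chrom, config, controlSex)
}

#' Call copy-number differences for a whole comparison
#'
#' The per-comparison driver: median-normalizes the log2 ratios, groups
#' primers into clusters (positional gaps, or gene annotation with
#' \code{noCluster}), prunes outliers and computes the weighted test and
#' scores per cluster, and classifies each cluster as gain, loss,
#' no_change or uncallable at the Q threshold. Entirely deterministic:
#' identical inputs give identical output.
#'
#' @param sample Count \code{data.frame} (\code{\link{readCountFile}}
#'   format) or an already-built \code{\link{AmpliconComparison}} (then
#'   \code{control} is ignored).
#' @param control Count \code{data.frame}, or a list of several control
#'   tables which are first averaged into one synthetic control
#'   (\code{\link{combineControls}}).
#' @param config A \code{\link{callerConfig}}.
#' @param sampleId,controlId,sampleSex,controlSex Passed to
#'   \code{\link{pairCounts}}.
#' @return A \code{\link{CnvCallSet}} sorted by (chrom, cluster start).
#' @export
callCnv <- function(sample, control = NULL, config = callerConfig(),
                    sampleId = "sample", controlId = "control",
                    sampleSex = "unknown", controlSex = "unknown") {
  if (methods::is(sample, "AmpliconComparison")) {
    comparison <- sample
  } else {
    if (is.null(control)) stop("control counts are required")
    if (is.data.frame(control)) control <- list(control)
    control <- combineControls(control)
    comparison <- pairCounts(sample, control, sampleId = sampleId,
                             controlId = controlId, sampleSex = sampleSex,
                             controlSex = controlSex)
  }
  comparison <- normalizeCounts(comparison)
  comparison <- if (config$noCluster) {
    assignClustersByGene(comparison)
  } else {
    assignClusters(comparison, minSplit = config$minSplit,
                   gapLarge = config$gapLarge, gapSmall = config$gapSmall,
                   smallCluster = config$smallCluster)
  }
  tab <- .clusterTable(comparison)
  idx <- attr(tab, "indices")
  xAll <- log2Ratios(comparison)
  wAll <- primerWeights(comparison)

  rows <- lapply(seq_len(nrow(tab)), function(k) {
    i <- idx[[k]]
    .callOne(xAll[i], wAll[i], tab$chrom[k], config, comparison@controlSex)
  })
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  gr <- GenomicRanges::GRanges(
    seqnames = factor(tab$chrom, levels = .orderedSeqlevels(tab$chrom)),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end)
  )
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    clusterId = tab$cluster, res)
  methods::new("CnvCallSet", calls = gr, config = unclass(config),
               sampleId = comparison@sampleId,
               controlId = comparison@controlId)
}
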