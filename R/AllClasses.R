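#' @import methods
#' @importFrom GenomicRanges GRanges mcols mcols<- start end seqnames strand
#'   findOverlaps granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom GenomeInfoDb sortSeqlevels seqlevels seqlevelsInUse
NULL

#' AmpliconComparison: paired sample/control primer counts
#'
#' Container for one sample-versus-control comparison on a shared multiplex
#' PCR primer panel. Each row of the underlying \code{GRanges} is one primer
#' site (width-1 range at the primer 5' position, strand = primer direction)
#' carrying the sample and control read counts and, after
#' \code{\link{normalizeCounts}}, the raw (\code{r}) and median-centred
#' (\code{x}) log2 count ratios. After \code{\link{assignClusters}} a
#' \code{cluster} label marks the calling unit each primer belongs to.
#'
#' @slot sites A \code{GRanges} of primer sites with metadata columns
#'   \code{name}, \code{gene}, \code{countSample}, \code{countControl}, and
#'   (once filled) \code{r}, \code{x}, \code{cluster}.
#' @slot sampleId,controlId Character labels for the two inputs.
#' @slot sampleSex,controlSex One of \code{"male"}, \code{"female"},
#'   \code{"unknown"}; only consulted for chrX/chrY clusters.
#' @slot normInfo List with \code{globalMedian} (the panel-wide median raw
#'   log2 ratio), \code{nUsed} and \code{nZeroAdjusted}; empty before
#'   normalization.
#'
#' @seealso \code{\link{pairCounts}}, \code{\link{normalizeCounts}},
#'   \code{\link{callCnv}}
#' @export
setClass("AmpliconComparison",
  slots = c(
    sites      = "GRanges",
    sampleId   = "character",
    controlId  = "character",
    sampleSex  = "character",
    controlSex = "character",
    normInfo   = "list"
  )
)

.validSex <- c("male", "female", "unknown")

setValidity("AmpliconComparison", function(object) {
  msg <- character()
  gr <- object@sites
  mc <- GenomicRanges::mcols(gr)
  need <- c("name", "gene", "countSample", "countControl")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("sites must carry metadata columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(mc$countSample < 0) || any(mc$countControl < 0))
      msg <- c(msg, "read counts must be non-negative")
  }
  if (length(gr) > 0) {
    if (any(GenomicRanges::start(gr) < 1))
      msg <- c(msg, "primer positions must be >= 1")
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
                 GenomicRanges::strand(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "primer sites must be unique by (chrom, pos, direction)")
    o <- order(as.integer(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "primer sites must be sorted by (chrom, pos)")
  }
  if (!object@sampleSex %in% .validSex || !object@controlSex %in% .validSex)
    msg <- c(msg, "sex must be one of male/female/unknown")
  if (length(msg)) msg else TRUE
})

#' CnvCallSet: per-cluster copy-number calls
#'
#' Result container produced by \code{\link{callCnv}}. The underlying
#' \code{GRanges} has one range per cluster (1-based inclusive span of its
#' primer positions) with all per-cluster statistics as metadata columns:
#' primer bookkeeping (\code{nPrimers} = n, \code{nKept} = n' after outlier
#' pruning), the weighted-statistics chain (\code{muStar}, \code{sigmaW2},
#' \code{nStar}, \code{se}, \code{tStat}, \code{pValue}, \code{phi}), the
#' scores (\code{qScore}, \code{pScore}), the copy-number estimate
#' (\code{nControl}, \code{copyNumber}, \code{cnMin}, \code{cnMax}), and the
#' classification (\code{status} in gain/loss/no_change/uncallable,
#' \code{passed} = Q at or above the threshold, \code{reason} for flags).
#'
#' @slot calls \code{GRanges} of cluster spans with the columns above.
#' @slot config The \code{\link{callerConfig}} list used for the run.
#' @slot sampleId,controlId Labels copied from the comparison.
#' @export
setClass("CnvCallSet",
  slots = c(
    calls     = "GRanges",
    config    = "list",
    sampleId  = "character",
    controlId = "character"
  )
)

setValidity("CnvCallSet", function(object) {
  mc <- GenomicRanges::mcols(object@calls)
  need <- c("clusterId", "nPrimers", "nKept", "nControl", "copyNumber",
            "cnMin", "cnMax", "muStar", "sigmaW2", "nStar", "se", "tStat",
            "pValue", "phi", "qScore", "pScore", "status", "passed", "reason")
  if (!all(need %in% colnames(mc)))
    return(paste("calls must carry metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object@calls) &&
      !all(mc$status %in% c("gain", "loss", "no_change", "uncallable")))
    return("invalid status value")
  TRUE
})

#' @describeIn AmpliconComparison Number of primer sites in the comparison.
#' @param x An \code{AmpliconComparison} or \code{CnvCallSet}.
#' @export
setMethod("length", "AmpliconComparison", function(x) length(x@sites))

#' @describeIn CnvCallSet Number of clusters in the call set.
#' @export
setMethod("length", "CnvCallSet", function(x) length(x@calls))

setMethod("show", "AmpliconComparison", function(object) {
  cat("AmpliconComparison:", object@sampleId, "vs", object@controlId, "\n")
  cat("  ", length(object@sites), " primer sites on ",
      length(GenomeInfoDb::seqlevelsInUse(object@sites)), " chromosome(s)\n",
      sep = "")
  cat("  sex: sample=", object@sampleSex, ", control=", object@controlSex,
      "\n", sep = "")
  if (length(object@normInfo)) {
    cat(sprintf("  normalized: global median r = %.4f (%d primers, %d zero-adjusted)\n",
                object@normInfo$globalMedian, object@normInfo$nUsed,
                object@normInfo$nZeroAdjusted))
  } else cat("  normalized: no\n")
  cl <- GenomicRanges::mcols(object@sites)$cluster
  if (!is.null(cl) && !all(is.na(cl)))
    cat("  clusters assigned:", length(unique(cl)), "\n")
})

setMethod("show", "CnvCallSet", function(object) {
  mc <- GenomicRanges::mcols(object@calls)
  cat("CnvCallSet:", object@sampleId, "vs", object@controlId, "\n")
  cat("  ", length(object@calls), " clusters; Q threshold ",
      object@config$qThreshold, "\n", sep = "")
  if (length(object@calls)) {
    tab <- table(factor(mc$status,
                        c("gain", "loss", "no_change", "uncallable")))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
})

#' Coerce a call set to a data.frame
#'
#' One row per cluster with coordinates and every statistic.
#'
#' @param x A \code{CnvCallSet}.
#' @param row.names,optional Passed through (unused).
#' @param ... Ignored.
#' @return A \code{data.frame}.
#' @export
#' @method as.data.frame CnvCallSet
as.data.frame.CnvCallSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  gr <- x@calls
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    as.data.frame(GenomicRanges::mcols(gr)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

setMethod("as.data.frame", "CnvCallSet", as.data.frame.CnvCallSet)
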