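#' @rdname accessors
#' @export
setGeneric("primerSites", function(x) standardGeneric("primerSites"))

#' @rdname accessors
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' @rdname accessors
#' @export
setGeneric("controlCounts", function(x) standardGeneric("controlCounts"))

#' @rdname accessors
#' @export
setGeneric("primerWeights", function(x) standardGeneric("primerWeights"))

#' @rdname accessors
#' @export
setGeneric("log2Ratios", function(x, normalized = TRUE)
  standardGeneric("log2Ratios"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("controlId", function(x) standardGeneric("controlId"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("clusterRanges", function(x) standardGeneric("clusterRanges"))

#' @rdname accessors
#' @export
setGeneric("qScores", function(x) standardGeneric("qScores"))

#' @rdname accessors
#' @export
setGeneric("pScores", function(x) standardGeneric("pScores"))

#' @rdname accessors
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))

#' @rdname accessors
#' @export
setGeneric("callStatus", function(x) standardGeneric("callStatus"))

#' Accessors for AmpliconComparison and CnvCallSet
#'
#' \code{primerSites} returns the primer-site \code{GRanges};
#' \code{sampleCounts}/\code{controlCounts} the per-primer read counts;
#' \code{primerWeights} the weights \eqn{w_i = C_{Si} + C_{Ci}};
#' \code{log2Ratios} the normalized (\code{x}, default) or raw (\code{r})
#' log2 ratios; \code{clusterIds} the per-primer (comparison) or per-call
#' cluster labels; \code{clusterRanges} the cluster spans of a call set;
#' \code{qScores}, \code{pScores}, \code{copyNumbers}, \code{callStatus}
#' the per-cluster results.
#'
#' @param x An \code{AmpliconComparison} or \code{CnvCallSet}.
#' @param normalized For \code{log2Ratios}: return median-centred \code{x}
#'   (\code{TRUE}) or raw \code{r} (\code{FALSE}).
#' @return Vectors or \code{GRanges} as described above.
#' @name accessors
NULL

#' @rdname accessors
setMethod("primerSites", "AmpliconComparison", function(x) x@sites)

#' @rdname accessors
setMethod("sampleCounts", "AmpliconComparison",
          function(x) GenomicRanges::mcols(x@sites)$countSample)

#' @rdname accessors
setMethod("controlCounts", "AmpliconComparison",
          function(x) GenomicRanges::mcols(x@sites)$countControl)

#' @rdname accessors
setMethod("primerWeights", "AmpliconComparison", function(x) {
  mc <- GenomicRanges::mcols(x@sites)
  mc$countSample + mc$countControl
})

#' @rdname accessors
setMethod("log2Ratios", "AmpliconComparison",
          function(x, normalized = TRUE) {
  if (!isNormalized(x))
    stop("comparison is not normalized; run normalizeCounts() first")
  mc <- GenomicRanges::mcols(x@sites)
  if (normalized) mc$x else mc$r
})

#' @rdname accessors
setMethod("isNormalized", "AmpliconComparison",
          function(x) length(x@normInfo) > 0)

#' @rdname accessors
setMethod("sampleId", "AmpliconComparison", function(x) x@sampleId)

#' @rdname accessors
setMethod("controlId", "AmpliconComparison", function(x) x@controlId)

#' @rdname accessors
setMethod("sampleId", "CnvCallSet", function(x) x@sampleId)

#' @rdname accessors
setMethod("controlId", "CnvCallSet", function(x) x@controlId)

#' @rdname accessors
setMethod("clusterIds", "AmpliconComparison",
          function(x) GenomicRanges::mcols(x@sites)$cluster)

#' @rdname accessors
setMethod("clusterIds", "CnvCallSet",
          function(x) GenomicRanges::mcols(x@calls)$clusterId)

#' @rdname accessors
setMethod("clusterRanges", "CnvCallSet", function(x) x@calls)

#' @rdname accessors
setMethod("qScores", "CnvCallSet",
          function(x) GenomicRanges::mcols(x@calls)$qScore)

#' @rdname accessors
setMethod("pScores", "CnvCallSet",
          function(x) GenomicRanges::mcols(x@calls)$pScore)

#' @rdname accessors
setMethod("copyNumbers", "CnvCallSet",
          function(x) GenomicRanges::mcols(x@calls)$copyNumber)

#' @rdname accessors
setMethod("callStatus", "CnvCallSet",
          function(x) GenomicRanges::mcols(x@calls)$status)
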