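# VCF 4.2 serialization of a CnvCallSet. One symbolic-ALT record per
# cluster: <DUP> for gains, <DEL> for losses, '.' for no_change. Q is the
# discriminating score and goes to QUAL; FILTER holds the categorical
# outcome derived from the threshold (PASS / q<threshold> / nocall),
# since VCF FILTER must be categorical. Output is fully deterministic
# (no timestamps), so identical runs are byte-identical.

.vcfFilterId <- function(qThreshold) sprintf("q%g", qThreshold)

.vcfHeader <- function(callSet) {
  cfg <- callSet@config
  fid <- .vcfFilterId(cfg$qThreshold)
  chroms <- GenomeInfoDb::seqlevels(callSet@calls)
  c("##fileformat=VCFv4.2",
    sprintf("##source=ampliCNV %s",
            as.character(utils::packageVersion("ampliCNV"))),
    sprintf("##sample=<ID=%s,Control=%s>", callSet@sampleId,
            callSet@controlId),
    "##ALT=<ID=DUP,Description=\"Copy number gain relative to control\">",
    "##ALT=<ID=DEL,Description=\"Copy number loss relative to control\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the cluster\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=CN,Number=1,Type=Float,Description=\"Estimated copy number in the sample\">",
    "##INFO=<ID=CNMIN,Number=1,Type=Float,Description=\"Lower confidence bound of CN\">",
    "##INFO=<ID=CNMAX,Number=1,Type=Float,Description=\"Upper confidence bound of CN\">",
    "##INFO=<ID=CNC,Number=1,Type=Integer,Description=\"Copy number in the control\">",
    "##INFO=<ID=PREC,Number=1,Type=Float,Description=\"Precision score P = -10*ln(SE)\">",
    "##INFO=<ID=NP,Number=1,Type=Integer,Description=\"Number of primers in the cluster (n)\">",
    "##INFO=<ID=NEP,Number=1,Type=Integer,Description=\"Number of primers kept after outlier pruning (n')\">",
    "##INFO=<ID=REASON,Number=1,Type=String,Description=\"Flag or uncallable reason\">",
    sprintf("##FILTER=<ID=%s,Description=\"Q score below %g\">", fid,
            cfg$qThreshold),
    "##FILTER=<ID=nocall,Description=\"Cluster not callable (see REASON)\">",
    sprintf("##contig=<ID=%s>", chroms),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write CNV calls as VCF 4.2
#'
#' One record per cluster: CHROM/POS = cluster span start, INFO END = span
#' end, ALT = \code{<DUP>} (gain), \code{<DEL>} (loss) or \code{.}
#' (no_change / uncallable), QUAL = Q rounded to two decimals, FILTER =
#' \code{PASS} when Q meets the threshold, otherwise \code{q<threshold>}
#' (\code{nocall} for uncallable clusters). INFO additionally carries
#' SVTYPE=CNV, CN with bounds CNMIN/CNMAX, the control copy number CNC,
#' the precision score PREC, primer counts NP (n) and NEP (n'), and a
#' REASON flag where applicable. Set \code{emitNoChange = FALSE} in the
#' config to restrict output to passing calls.
#'
#' @param callSet A \code{\link{CnvCallSet}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCnvVcf <- function(callSet, path) {
  stopifnot(methods::is(callSet, "CnvCallSet"))
  cfg <- callSet@config
  gr <- callSet@calls
  mc <- GenomicRanges::mcols(gr)
  lines <- .vcfHeader(callSet)
  keep <- if (isTRUE(cfg$emitNoChange)) seq_along(gr) else which(mc$passed)
  if (length(keep)) {
    alt <- c(gain = "<DUP>", loss = "<DEL>", no_change = ".",
             uncallable = ".")[mc$status[keep]]
    qual <- ifelse(is.na(mc$qScore[keep]), ".",
                   sprintf("%.2f", mc$qScore[keep]))
    filter <- ifelse(mc$status[keep] == "uncallable", "nocall",
                     ifelse(mc$passed[keep], "PASS",
                            .vcfFilterId(cfg$qThreshold)))
    info <- vapply(keep, function(i) {
      f <- c(sprintf("END=%d", GenomicRanges::end(gr)[i]), "SVTYPE=CNV")
      if (!is.na(mc$copyNumber[i]))
        f <- c(f, sprintf("CN=%s", .fmtNum(mc$copyNumber[i])),
               sprintf("CNMIN=%s", .fmtNum(mc$cnMin[i])),
               sprintf("CNMAX=%s", .fmtNum(mc$cnMax[i])),
               sprintf("CNC=%d", mc$nControl[i]))
      if (!is.na(mc$pScore[i]))
        f <- c(f, sprintf("PREC=%s", .fmtNum(mc$pScore[i], 2)))
      f <- c(f, sprintf("NP=%d", mc$nPrimers[i]))
      if (!is.na(mc$nKept[i])) f <- c(f, sprintf("NEP=%d", mc$nKept[i]))
      if (nzchar(mc$reason[i]))
        f <- c(f, sprintf("REASON=%s", mc$reason[i]))
      paste(f, collapse = ";")
    }, character(1))
    lines <- c(lines, paste(
      as.character(GenomicRanges::seqnames(gr))[keep],
      GenomicRanges::start(gr)[keep],
      mc$clusterId[keep], "N", alt, qual, filter, info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
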