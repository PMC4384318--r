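# Internal helpers: structured stderr logging and chromosome name handling.

.log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

.logWarn <- function(...) .log("WARN", ...)
.logInfo <- function(...) .log("INFO", ...)

# "chr7" -> "7", "chrX"/"X"/"x" -> "X"
.chromKey <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE))
}

# Natural chromosome order for deterministic sorting of arbitrary names.
.orderedSeqlevels <- function(chroms) {
  GenomeInfoDb::sortSeqlevels(unique(as.character(chroms)))
}

.fmtNum <- function(x, digits = 4) {
  ifelse(is.na(x) | !is.finite(x), ".",
         formatC(x, format = "f", digits = digits, drop0trailing = TRUE))
}
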