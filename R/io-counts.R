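#' Read a per-primer count file
#'
#' Parses the tab-separated per-primer count format: one row per primer with
#' columns \code{chrom}, \code{pos} (1-based primer 5' position),
#' \code{direction} (\code{+}/\code{-}), \code{name}, \code{count} and an
#' optional sixth column \code{gene} (the cluster label used by
#' gene-annotation mode). Lines starting with \code{#} are comments.
#'
#' Counts are usually integers straight from primer-trimming, but fractional
#' values are accepted so that an averaged multi-control table written with
#' \code{\link{writeCountFile}} can be re-read losslessly.
#'
#' @param path Path to the count file.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{direction}, \code{name}, \code{count}, \code{gene} (NA when the
#'   column is absent), one row per data line in file order.
#' @export
readCountFile <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(chrom = character(), pos = integer(),
                      direction = character(), name = character(),
                      count = numeric(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield < 5)
  if (length(bad))
    stop(sprintf("%s: line %d: expected >= 5 tab-separated columns, got %d",
                 path, idx[bad[1]], nfield[bad[1]]))
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- getcol(1)
  posS <- getcol(2)
  direction <- getcol(3)
  name <- getcol(4)
  countS <- getcol(5)
  gene <- ifelse(nfield >= 6,
                 vapply(fields, function(f) if (length(f) >= 6) f[[6]] else NA_character_,
                        character(1)),
                 NA_character_)
  gene[!is.na(gene) & !nzchar(gene)] <- NA_character_

  pos <- suppressWarnings(as.numeric(posS))
  count <- suppressWarnings(as.numeric(countS))
  .lineErr <- function(i, what, val)
    stop(sprintf("%s: line %d: %s ('%s')", path, idx[i], what, val))
  if (anyNA(pos) || any(pos != floor(pos)) || any(pos < 1)) {
    i <- which(is.na(pos) | pos != floor(pos) | pos < 1)[1]
    .lineErr(i, "position must be a positive integer", posS[i])
  }
  if (anyNA(count) || any(count < 0)) {
    i <- which(is.na(count) | count < 0)[1]
    .lineErr(i, "count must be a non-negative number", countS[i])
  }
  if (any(!direction %in% c("+", "-"))) {
    i <- which(!direction %in% c("+", "-"))[1]
    .lineErr(i, "direction must be '+' or '-'", direction[i])
  }
  if (any(!nzchar(chrom))) {
    i <- which(!nzchar(chrom))[1]
    .lineErr(i, "chromosome must be non-empty", chrom[i])
  }
  data.frame(chrom = chrom, pos = as.integer(pos), direction = direction,
             name = name, count = count, gene = gene,
             stringsAsFactors = FALSE)
}

#' Write a per-primer count file
#'
#' Inverse of \code{\link{readCountFile}}; the \code{gene} column is written
#' only when at least one row has one.
#'
#' @param counts A \code{data.frame} as returned by \code{readCountFile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCountFile <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tdirection\tname\tcount\tgene", con)
  hasGene <- "gene" %in% names(counts) && any(!is.na(counts$gene))
  cnt <- counts$count
  cntS <- ifelse(cnt == round(cnt), format(round(cnt), scientific = FALSE,
                                           trim = TRUE),
                 formatC(cnt, format = "g", digits = 15))
  base <- paste(counts$chrom, counts$pos, counts$direction, counts$name,
                cntS, sep = "\t")
  if (hasGene)
    base <- paste(base, ifelse(is.na(counts$gene), "", counts$gene),
                  sep = "\t")
  writeLines(base, con)
  invisible(path)
}

#' Average several control count tables into one synthetic control
#'
#' Per primer site, the synthetic control count is the arithmetic mean of
#' the controls' counts, kept fractional (rounding would bias low-count
#' primers). All controls must cover the identical panel.
#'
#' @param controls A list of count \code{data.frame}s
#'   (\code{\link{readCountFile}} format), all over the same primer sites.
#' @return A count \code{data.frame} with the layout of the first control
#'   and averaged counts.
#' @export
combineControls <- function(controls) {
  stopifnot(is.list(controls), length(controls) >= 1)
  if (length(controls) == 1) return(controls[[1]])
  ref <- controls[[1]]
  key <- function(df) paste(df$chrom, df$pos, df$direction, sep = "\r")
  refKey <- key(ref)
  if (anyDuplicated(refKey)) stop("duplicate primer sites in control table")
  acc <- ref$count
  for (k in seq_along(controls)[-1]) {
    ctl <- controls[[k]]
    m <- match(refKey, key(ctl))
    if (anyNA(m)) {
      miss <- which(is.na(m))[1]
      stop(sprintf("control %d is missing primer site %s:%d(%s)",
                   k, ref$chrom[miss], ref$pos[miss], ref$direction[miss]))
    }
    if (nrow(ctl) > nrow(ref)) {
      extra <- setdiff(key(ctl), refKey)
      stop(sprintf("control %d has %d primer site(s) absent from control 1",
                   k, length(extra)))
    }
    acc <- acc + ctl$count[m]
  }
  out <- ref
  out$count <- acc / length(controls)
  out
}

#' Pair sample and control counts into a comparison
#'
#' Matches primer sites by \code{(chrom, pos, direction)} — names are free
#' text and not trusted — keeping the intersection of the two panels.
#' Sites present in only one input are dropped with a WARN log line; an
#' empty intersection is an error because sample and control must be
#' enriched with the identical primer panel.
#'
#' @param sample,control Count \code{data.frame}s from
#'   \code{\link{readCountFile}} (control possibly from
#'   \code{\link{combineControls}}).
#' @param sampleId,controlId Labels for reporting.
#' @param sampleSex,controlSex \code{"male"}, \code{"female"} or
#'   \code{"unknown"} (default); required only to call chrX/chrY clusters.
#' @return An \code{\link{AmpliconComparison}} sorted by (chrom, pos).
#' @export
pairCounts <- function(sample, control, sampleId = "sample",
                       controlId = "control", sampleSex = "unknown",
                       controlSex = "unknown") {
  if (!nrow(sample) || !nrow(control))
    stop("sample and control count tables must be non-empty")
  kS <- paste(sample$chrom, sample$pos, sample$direction, sep = "\r")
  kC <- paste(control$chrom, control$pos, control$direction, sep = "\r")
  if (anyDuplicated(kS)) stop("duplicate primer sites in sample table")
  if (anyDuplicated(kC)) stop("duplicate primer sites in control table")
  m <- match(kS, kC)
  inBoth <- !is.na(m)
  if (!any(inBoth))
    stop("panels do not match: no primer site shared between sample and control")
  dropS <- sum(!inBoth)
  dropC <- nrow(control) - sum(inBoth)
  if (dropS > 0)
    .logWarn(dropS, " sample primer site(s) absent from control; dropped")
  if (dropC > 0)
    .logWarn(dropC, " control primer site(s) absent from sample; dropped")
  s <- sample[inBoth, , drop = FALSE]
  cc <- control$count[m[inBoth]]
  gene <- if ("gene" %in% names(s)) s$gene else NA_character_

  lv <- .orderedSeqlevels(s$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(s$chrom, levels = lv),
    ranges = IRanges::IRanges(start = s$pos, width = 1L),
    strand = s$direction,
    name = s$name,
    gene = gene,
    countSample = as.numeric(s$count),
    countControl = as.numeric(cc),
    r = NA_real_, x = NA_real_, cluster = NA_character_
  )
  gr <- gr[order(as.integer(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  methods::new("AmpliconComparison", sites = gr, sampleId = sampleId,
               controlId = controlId, sampleSex = sampleSex,
               controlSex = controlSex, normInfo = list())
}
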