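#' Raw log2 count ratio for one primer
#'
#' \eqn{r_i = \log_2(C_{Si} / C_{Ci})}. Both counts must be positive; zero
#' counts are handled upstream by the continuity correction in
#' \code{\link{normalizeCounts}}.
#'
#' @param cSample,cControl Positive read counts.
#' @return The log2 ratio (vectorized).
#' @export
rawLog2Ratio <- function(cSample, cControl) {
  if (any(cSample < 0) || any(cControl < 0))
    stop("read counts must be non-negative")
  if (any(cSample == 0) || any(cControl == 0))
    stop("zero counts must be continuity-corrected before taking ratios")
  log2(cSample / cControl)
}

#' Median-normalize log2 ratios across a comparison
#'
#' Computes the raw ratio \eqn{r_i = \log_2(C_{Si}/C_{Ci})} per primer, the
#' global median \eqn{\tilde r} over \emph{all} primers of the comparison
#' (not per cluster), and the normalized ratio \eqn{x_i = r_i - \tilde r}.
#' The median removes library-size and global-efficiency differences under
#' the assumption that fewer than half of all primers sit in copy-number
#' changed regions, so the median ratio reflects an unchanged locus.
#'
#' Zero counts, for which the ratio is undefined, receive a continuity
#' correction: the zero side is set to 0.5. This keeps homozygous-deletion
#' primers (the most informative ones) in the data rather than dropping
#' them; implausible resulting ratios are still subject to per-cluster
#' outlier pruning. The number of adjusted primers is recorded.
#'
#' @param comparison An \code{\link{AmpliconComparison}}.
#' @return The comparison with \code{r} and \code{x} filled in and
#'   \code{normInfo} set (\code{globalMedian}, \code{nUsed},
#'   \code{nZeroAdjusted}).
#' @export
normalizeCounts <- function(comparison) {
  stopifnot(methods::is(comparison, "AmpliconComparison"))
  if (!length(comparison)) stop("cannot normalize an empty comparison")
  mc <- GenomicRanges::mcols(comparison@sites)
  cs <- mc$countSample
  cc <- mc$countControl
  zero <- (cs == 0) | (cc == 0)
  cs[cs == 0] <- 0.5
  cc[cc == 0] <- 0.5
  r <- log2(cs / cc)
  rTilde <- stats::median(r)
  mc$r <- r
  mc$x <- r - rTilde
  GenomicRanges::mcols(comparison@sites) <- mc
  comparison@normInfo <- list(globalMedian = rTilde, nUsed = length(r),
                              nZeroAdjusted = sum(zero))
  comparison
}
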