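# Seeded synthetic amplicon-count generator. Emulates multiplex-PCR
# enrichment data: a panel of gene clusters scattered across autosomes,
# per-amplicon PCR efficiency shared between sample and control,
# negative-binomial (overdispersed) counts, planted integer copy-number
# events per cluster, and occasional sample-only efficiency shifts
# mimicking primer-site variants.

#' Build a synthetic amplicon panel layout
#'
#' Lays out \code{nClusters} gene clusters over the autosomes, cycling
#' chr1..chr22, with cluster start positions spaced \code{clusterSpacing}
#' apart on the same chromosome (default 2 Mbp, comfortably above the
#' positional-splitting thresholds) and amplicon 5' positions tiled
#' \code{spacing} apart within a cluster (default 150 bp, matching
#' 120-180 bp amplicons). Each cluster carries a gene label
#' (\code{GENE001}, ...) so gene-annotation mode works on the same panel.
#'
#' @param nClusters Number of clusters (default 40, a typical custom CNV
#'   panel).
#' @param ampliconsPerCluster Amplicons per cluster (default 40).
#' @param spacing Distance between adjacent amplicon positions (bp).
#' @param clusterSpacing Distance between cluster starts on a chromosome.
#' @param chroms Chromosome names to cycle over.
#' @return A \code{data.frame} with one row per cluster: \code{cluster},
#'   \code{gene}, \code{chrom}, \code{start}, \code{n}, \code{spacing}.
#' @export
makePanel <- function(nClusters = 40L, ampliconsPerCluster = 40L,
                      spacing = 150L, clusterSpacing = 2000000L,
                      chroms = paste0("chr", 1:22)) {
  stopifnot(nClusters >= 1, ampliconsPerCluster >= 1, spacing > 0)
  k <- seq_len(nClusters)
  chrom <- chroms[((k - 1) %% length(chroms)) + 1]
  rankOnChrom <- ave(k, chrom, FUN = seq_along)
  data.frame(
    cluster = sprintf("sim%03d", k),
    gene = sprintf("GENE%03d", k),
    chrom = chrom,
    start = 1000000L + (rankOnChrom - 1L) * as.integer(clusterSpacing),
    n = as.integer(ampliconsPerCluster),
    spacing = as.integer(spacing),
    stringsAsFactors = FALSE
  )
}

#' Simulate a sample/control amplicon-count comparison with known truth
#'
#' Per amplicon \eqn{i} of the panel, a shared PCR efficiency
#' \eqn{e_i = 2^{N(0, \mathrm{efficiencySd}^2)}} multiplies both means;
#' counts are drawn as NegBin(mean = depth * e_i * N/2, size =
#' dispersion) with N the true copy number of the amplicon's cluster in
#' control (\eqn{N_C}) and sample (\eqn{N_S}). With probability
#' \code{outlierRate} an amplicon gets a sample-only efficiency shift
#' (mostly downward, as primer-site variants impair binding): a
#' multiplier \eqn{2^{\pm U(1,3)}} with sign - at probability 0.8.
#' \code{clusterBiasSd} (default 0 = off) adds a per-cluster sample-side
#' log2 bias \eqn{N(0, \mathrm{clusterBiasSd}^2)} emulating residual
#' handling/efficiency differences between the sample and control
#' libraries.
#'
#' @param panel Panel layout from \code{\link{makePanel}}.
#' @param truth Optional \code{data.frame} with columns \code{cluster},
#'   \code{nControl}, \code{nSample}; clusters not listed are (2, 2).
#' @param depth Target mean per-amplicon count at 2 copies (default
#'   1000, mid-range for MPE runs at 500-2000x).
#' @param efficiencySd SD of the shared per-amplicon log2 efficiency
#'   (default 0.15).
#' @param dispersion Negative-binomial size parameter; scalar or one
#'   value per cluster (default 80; smaller = more overdispersed).
#' @param outlierRate Per-amplicon probability of a sample-only shift
#'   (default 0.02; must stay below 1/3, the pruning cap).
#' @param clusterBiasSd SD of the per-cluster sample-side log2 bias
#'   (default 0).
#' @param seed Integer seed; the generator is fully reproducible and
#'   leaves the global RNG state untouched.
#' @return A list with \code{sample} and \code{control} count
#'   \code{data.frame}s (\code{\link{readCountFile}} layout, gene column
#'   filled) and \code{truth} (\code{cluster}, \code{gene}, \code{chrom},
#'   \code{start}, \code{end}, \code{nControl}, \code{nSample}).
#' @export
simulateComparison <- function(panel, truth = NULL, depth = 1000,
                               efficiencySd = 0.15, dispersion = 80,
                               outlierRate = 0.02, clusterBiasSd = 0,
                               seed = 1L) {
  stopifnot(depth > 0, efficiencySd >= 0, all(dispersion > 0),
            outlierRate >= 0, outlierRate < 1 / 3, clusterBiasSd >= 0)
  nC <- rep(2L, nrow(panel))
  nS <- rep(2L, nrow(panel))
  if (!is.null(truth)) {
    m <- match(truth$cluster, panel$cluster)
    if (anyNA(m)) stop("truth refers to unknown cluster(s): ",
                       paste(truth$cluster[is.na(m)], collapse = ", "))
    nC[m] <- truth$nControl
    nS[m] <- truth$nSample
  }
  disp <- rep_len(dispersion, nrow(panel))

  rows <- withr::with_seed(seed, {
    lapply(seq_len(nrow(panel)), function(k) {
      n <- panel$n[k]
      pos <- panel$start[k] + (seq_len(n) - 1L) * panel$spacing[k]
      eff <- 2^stats::rnorm(n, 0, efficiencySd)
      bias <- if (clusterBiasSd > 0) 2^stats::rnorm(1, 0, clusterBiasSd) else 1
      isOut <- stats::runif(n) < outlierRate
      shift <- rep(1, n)
      if (any(isOut)) {
        sgn <- ifelse(stats::runif(sum(isOut)) < 0.8, -1, 1)
        shift[isOut] <- 2^(sgn * stats::runif(sum(isOut), 1, 3))
      }
      muC <- depth * eff * nC[k] / 2
      muS <- depth * eff * nS[k] / 2 * shift * bias
      data.frame(
        chrom = panel$chrom[k],
        pos = pos,
        direction = rep_len(c("+", "-"), n),
        name = sprintf("%s_%03d", panel$gene[k], seq_len(n)),
        countControl = stats::rnbinom(n, size = disp[k], mu = muC),
        countSample = stats::rnbinom(n, size = disp[k], mu = muS),
        gene = panel$gene[k],
        cluster = panel$cluster[k],
        stringsAsFactors = FALSE
      )
    })
  })
  all <- do.call(rbind, rows)
  counts <- function(col) data.frame(
    chrom = all$chrom, pos = all$pos, direction = all$direction,
    name = all$name, count = as.numeric(all[[col]]), gene = all$gene,
    stringsAsFactors = FALSE)
  truthTab <- data.frame(
    cluster = panel$cluster, gene = panel$gene, chrom = panel$chrom,
    start = panel$start,
    end = panel$start + (panel$n - 1L) * panel$spacing,
    nControl = nC, nSample = nS, stringsAsFactors = FALSE)
  list(sample = counts("countSample"), control = counts("countControl"),
       truth = truthTab)
}

#' Write a simulated truth table as TSV
#'
#' @param truth Truth \code{data.frame} from
#'   \code{\link{simulateComparison}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
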