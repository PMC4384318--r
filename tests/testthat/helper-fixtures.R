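# Shared fixture builders. Everything is generated in code; no data files.

suppressPackageStartupMessages(library(GenomicRanges))

# A minimal count data.frame in readCountFile() layout.
countTable <- function(chrom, pos, count, direction = "+",
                       name = sprintf("amp%03d", seq_along(pos)),
                       gene = NA_character_) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             direction = rep_len(direction, length(pos)),
             name = rep_len(name, length(pos)),
             count = as.numeric(count),
             gene = rep_len(gene, length(pos)),
             stringsAsFactors = FALSE)
}

# Paired comparison over one shared site layout.
makeComparison <- function(chrom, pos, cSample, cControl, gene = NA,
                           sampleSex = "unknown", controlSex = "unknown") {
  pairCounts(countTable(chrom, pos, cSample, gene = gene),
             countTable(chrom, pos, cControl, gene = gene),
             sampleSex = sampleSex, controlSex = controlSex)
}

# Brute-force (loop-based) oracles for the weighted statistics chain,
# kept deliberately naive and independent of the package implementation.
naiveWeightedMean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + w[i] * x[i]; den <- den + w[i] }
  num / den
}
naiveWeightedVariance <- function(x, w, mu) {
  num <- 0; W <- 0
  for (i in seq_along(x)) { num <- num + w[i] * (x[i] - mu)^2; W <- W + w[i] }
  num / (W - 1)
}
naiveEffectiveN <- function(w) {
  s <- 0; s2 <- 0
  for (i in seq_along(w)) { s <- s + w[i]; s2 <- s2 + w[i]^2 }
  s^2 / s2
}

# t CDF by numerical integration of the density (independent of pt()).
# Integrated from the nearer tail so quadrature never misses the peak.
tTailProb <- function(q, df) {
  if (q > 0) return(1 - tTailProb(-q, df))
  stats::integrate(function(u) stats::dt(u, df), -Inf, q,
                   rel.tol = 1e-12)$value
}
# t quantile by root-finding on the integrated CDF (independent of qt()).
tQuantile <- function(p, df) {
  stats::uniroot(function(q) tTailProb(q, df) - p, c(-200, 200),
                 tol = 1e-12)$root
}
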