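---
title: "Calling copy-number differences from amplicon read counts"
author: "ampliCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number differences from amplicon read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliCNV)
```

## The measurement model

Multiplex PCR enrichment (MPE) sequences a panel of hundreds to thousands
of short amplicons (typically 120–180 bp) covering exons of a limited set
of genes scattered across the genome. The read count of each amplicon is
a proxy for the local copy number of its template, but it is a noisy one:
per-amplicon PCR efficiency varies strongly and is determined mostly by
the amplicon sequence itself. The key observation exploited here is that
this efficiency is *shared* between a sample and a control enriched with
the identical primer pool, so the per-primer ratio

$$r_i = \log_2\frac{C_{Si}}{C_{Ci}}$$

cancels the efficiency while retaining the copy-number signal. Everything
downstream works on these ratios; no GC, length or library-size model is
fitted. The flip side is that sample and control **must** be enriched
with the same panel — `pairCounts()` refuses inputs with no shared
primer sites, and drops (with a warning) sites present on only one side.

### Normalization

Library size and global efficiency differences shift all $r_i$ by a
constant. `normalizeCounts()` removes it with the panel-wide median:
$x_i = r_i - \tilde r$. The median is a robust diploid reference only
when fewer than half of all primers sit in changed regions; panels
should be designed accordingly (the simulator plants events on at most a
quarter of clusters for the same reason). Zero counts, for which the
ratio is undefined, get a continuity correction of 0.5 on the zero side
only. This keeps homozygous-deletion primers — the most informative
ones — in the data; a grossly implausible ratio that results from a
technical dropout is still caught later by outlier pruning.

### Clustering

MPE data are dense inside targeted regions and empty between them, so
segmentation is meaningless; instead each positional cluster of
amplicons is assumed to carry one copy-number state and is called as a
unit. `assignClusters()` starts with one cluster per chromosome and
recursively splits at the largest qualifying gap between adjacent primer
positions:

* a split must leave at least 10 primers on both sides, **or** the gap
  must exceed 250 kbp;
* clusters with fewer than 100 primers are additionally only split at
  gaps of at least 100 kbp.

Gaps are compared on primer 5′ positions; at the 100–250 kbp scales
involved, the difference from end-to-start distances (amplicons are
120–180 bp) is negligible. When several gaps tie for largest, the
leftmost wins, making the partition deterministic. The recursion
re-checks the rules on every child, so the final partition is a fixpoint:
re-clustering any produced cluster leaves it intact. The published rule
text does not fully pin down how the two conditions interact for small
clusters; this implementation treats the 100 kbp condition as
*necessary* for clusters under 100 members (such a cluster is never
split at a smaller gap, however many members each side would keep),
which is the conservative reading. `--no-cluster` mode
(`assignClustersByGene()`) replaces all of this with one cluster per
(chromosome, gene) label, useful when target regions are defined by
annotation.

### Outlier pruning

True outliers — primer-binding-site variants, mapping losses around
indels, aberrant efficiencies — are not distributional noise and would
corrupt a mean-based test. `removeOutliers()` iterates a Shapiro–Wilk
test on each cluster's $x$ values: while normality is rejected at
p ≤ 0.05, the element farthest from the *weighted* mean is dropped and
the test repeated, removing at most ⌊n/3⌋ elements. The Shapiro–Wilk
test sees the plain (unweighted) ratios; the removal criterion uses the
count-weighted mean, recomputed each round on the surviving subset. Ties
on the distance go to the smaller weight, then to the earlier genomic
position. Clusters still rejected at the cap are flagged
(`outlier_cap_hit`) rather than pruned further.

### Weighted test statistics

Ratios from deeply covered primers are more reliable, so each primer is
weighted by its total evidence $w_i = C_{Si} + C_{Ci}$. With
$W = \sum w_i$ over the kept subset:

$$\mu^* = \frac{1}{W}\sum_i w_i x_i,\qquad
  \sigma_w^2 = \frac{1}{W-1}\sum_i w_i\,(x_i-\mu^*)^2,\qquad
  n^* = \frac{(\sum_i w_i)^2}{\sum_i w_i^2}$$

The individual read counts are treated as repeated draws of the
primer-extension event, hence the $W-1$ (not $n-1$) bias correction in
$\sigma_w^2$. The effective sample size $n^*$ is the equivalent number
of equally weighted observations: it equals the number of primers when
weights are equal and shrinks as they diverge. The null hypothesis of no
difference ($\mu^* = 0$, since $C_S = C_C$ gives $\log_2 1 = 0$) is
tested with

$$t = \sqrt{n^*}\,\frac{\mu^*-\mu_0}{\sigma_w},\qquad
  p = 2\,\Pr\!\left(T_{n^*} \le -|t|\right),$$

while the confidence bound for $\mu^*$ uses
$SE_{\mu^*} = z(1-\alpha/2,\,n^*-1)\,\sigma_w/\sqrt{n^*}$ with $z$ the
t-distribution quantile (fractional degrees of freedom are allowed). The
degrees of freedom deliberately differ — $n^*$ for the test, $n^*-1$ for
the bound — matching the method as published; with unit weights the
chain collapses to the classic one-sample t statistic (the test suite
asserts this exactly).

### Scores and the call decision

The copy number follows from the control's copy number $N_C$ (2 on
autosomes; on chrX/chrY determined by the stated sex, and uncallable
when the sex is unknown or $N_C = 0$):

$$N_S = N_C \cdot 2^{\mu^*},\qquad
  N_{S(\min,\max)} = N_C \cdot 2^{\mu^* \pm SE_{\mu^*}}.$$

$N_S$ stays real-valued on purpose — a 3.5 still counts as a gain, and
mosaicism or impure samples genuinely produce fractional values.

Raw p-values discriminate poorly on real panels: clusters with
suspiciously low dispersion reach extreme p-values from tiny absolute
shifts (false positives), while genuinely changed clusters with high
dispersion rarely reach significance (false negatives). The dispersion
factor

$$\phi = \sqrt{\sigma_w}\,(1 + |\mu^*|)$$

corrects both directions at once, and folds the effect size in so that
no separate log2-ratio cutoff is needed. (The radicand is the weighted
standard deviation, exactly as the formula is printed in the method's
original description, even though its prose mentions the standard
error.) The reported scores are

$$Q = -10\log_{10}(p)\cdot\phi,\qquad P = -10\ln(SE_{\mu^*}),$$

with a call made at Q ≥ 50. p-values below the smallest representable
double are clamped to it before the log — Q is a ranking score, not an
inferential quantity, and a finite ceiling beats an infinity. P
summarizes estimate precision: the simulations in the test suite confirm
that calls with P > 20 essentially always land within 20 % of the true
copy number (and P > 30 within 10 %). Two degenerate outcomes are worth
knowing: a perfectly flat cluster ($\sigma_w = 0$) has $\phi = 0$ and
therefore Q = 0 — it can never be called even at $\mu^* \ne 0$, and is
flagged `zero_dispersion`; clusters with fewer than 10 usable primers
after pruning are `uncallable` rather than weakly called.

## Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `qThreshold` | 50 | minimum Q (Phred-like) for a call |
| `alpha` | 0.05 | level for $SE_{\mu^*}$ / CN bounds |
| `swAlpha` | 0.05 | Shapiro–Wilk rejection level |
| `minCluster` | 10 | minimum usable primers ($n'$) per callable cluster |
| `gapLarge` | 250 kbp | gap that always splits (strictly greater) |
| `gapSmall` | 100 kbp | minimum gap to split a <100-primer cluster |
| `smallCluster` | 100 | size below which `gapSmall` applies |
| `minSplit` | 10 | minimum members each side of an ordinary split |

Sexes default to `unknown`: autosomes are always callable, chrX/chrY
stay uncallable until sexes are supplied — safer than silently assuming
a diploid X.

## The synthetic-data model

`simulateComparison()` generates count tables with known truth so the
whole pipeline is testable without sequencing data. Per amplicon, a
shared efficiency $e_i = 2^{N(0,\,0.15^2)}$ multiplies both means, and
counts are drawn from a negative binomial with mean
$\text{depth}\cdot e_i \cdot N/2$ and size 80. The choices, made once:

* **depth 1000** — the middle of typical MPE runs (medium-coverage runs
  around 500–1000×, high-coverage around 1500–2000×);
* **efficiency SD 0.15 (log2)** — a ±10 % to ±25 % efficiency band,
  shared sample/control, reproducing the correlated depth structure the
  weighting $w_i = C_{Si}+C_{Ci}$ exploits;
* **negative binomial, size 80** — PCR replication noise beyond Poisson;
  at depth 1000 this gives a per-count CV of ~12 %, i.e. within-cluster
  log2-ratio SD around 0.24;
* **outlier rate 0.02** — sample-only efficiency shifts $2^{\pm U(1,3)}$,
  downward with probability 0.8, mimicking primer-site variants that
  impair binding (occasionally over-amplification);
* **`clusterBiasSd` 0 (off)** — an optional per-cluster sample-side log2
  bias emulating residual handling differences between libraries; it is
  switched on (0.08) only in the dispersion-correction ablation, where
  heterogeneous per-cluster dispersion (NB size 10 vs 1000) plus this
  bias reproduces exactly the failure mode $\phi$ was designed for:
  low-dispersion null clusters reaching extreme p-values while
  high-dispersion events stay moderate.

What the simulator does **not** model: GC- or length-dependent bias
(deliberately — the method claims robustness without bias models, but
passing simulations cannot prove that claim for real bias structures),
mappability artifacts, read-level noise (no FASTQ), partial-cluster
events (the caller assumes one state per cluster and simulations honor
that assumption), and sample purity. Results on simulated data therefore
validate the statistical machinery and its operating characteristics
under the stated noise model, not performance on any particular
wet-lab panel.

## Problem sizes used by the test suite

The packaged checks run, as the package's own choice of scale: 24
replicate panels of 40 clusters × 40 amplicons at depth 1000 (240
single-copy events, 720 unchanged clusters) for
sensitivity/specificity and P > 20 calibration; 4 panels of 20 clusters
× 100 amplicons at depth 2000 for the P > 30 regime; 5 panels of 40
clusters × 15 amplicons for the dispersion-correction ablation; and
1000-case randomized oracles for the equation layer. `benchmarkCaller()`
reproduces the first of these directly, and `scripts/acceptance.R`
recomputes all of them from scratch.

## Known limitations

* No intra-cluster segmentation: an event with a breakpoint inside a
  cluster yields a diluted, inaccurate estimate.
* Clusters need at least 10 usable, approximately normal primer ratios;
  smaller ones are reported `uncallable`, never weakly called.
* No purity estimation: $N_S$ is the average over the DNA in the tube.
* Identical primer panels for sample and control are mandatory; the
  tool enforces site intersection but cannot rescue disjoint designs.
* The Q threshold is a fixed operating point, not an FDR control across
  clusters.
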