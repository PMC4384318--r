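# Per-cluster statistical core: count-weighted moments, effective sample
# size, weighted one-sample t-test, dispersion-corrected Q score and
# precision P score.

#' Count-weighted mean
#'
#' \eqn{\mu^* = (1/W) \sum_i w_i x_i} with \eqn{W = \sum_i w_i}. Weights
#' are the summed sample+control read counts, so primers measured at
#' higher depth contribute proportionally more.
#'
#' @param x Normalized log2 ratios.
#' @param w Positive weights, same length.
#' @return The weighted mean.
#' @export
weightedMean <- function(x, w) {
  if (!length(x)) stop("empty input")
  if (length(x) != length(w)) stop("x and w must have equal length")
  if (any(w <= 0)) stop("weights must be positive")
  sum(w * x) / sum(w)
}

#' Unbiased count-weighted variance
#'
#' \eqn{\sigma_w^2 = \sum_i w_i (x_i - \mu^*)^2 / (W - 1)} where \eqn{W}
#' is the sum of the count weights. The denominator treats the individual
#' read counts as repeated draws of the primer-extension event, so the
#' bias correction is \eqn{W - 1}, not \eqn{n - 1}.
#'
#' @param x Normalized log2 ratios.
#' @param w Positive weights with \eqn{W = \sum w > 1}.
#' @param muStar The weighted mean of \code{x} (see
#'   \code{\link{weightedMean}}).
#' @return The weighted variance.
#' @export
weightedVariance <- function(x, w, muStar = weightedMean(x, w)) {
  if (!length(x)) stop("empty input")
  if (length(x) != length(w)) stop("x and w must have equal length")
  if (any(w <= 0)) stop("weights must be positive")
  W <- sum(w)
  if (W <= 1) stop("sum of weights must exceed 1")
  sum(w * (x - muStar)^2) / (W - 1)
}

#' Effective sampling size under unequal weights
#'
#' \eqn{n^* = (\sum_i w_i)^2 / \sum_i w_i^2}: the number of equally
#' weighted observations carrying the same information. Equals the number
#' of primers when all weights are equal and is always at most that
#' number.
#'
#' @param w Positive weights.
#' @return The effective sample size (real, in \eqn{(0, n]}).
#' @export
effectiveN <- function(w) {
  if (!length(w)) stop("empty input")
  if (any(w <= 0)) stop("weights must be positive")
  sum(w)^2 / sum(w^2)
}

#' Standard error of the weighted mean
#'
#' \eqn{SE_{\mu^*} = z(1 - \alpha/2,\; n^* - 1)\; \sigma_w / \sqrt{n^*}}
#' where \eqn{z} is the quantile function of the t distribution
#' (fractional degrees of freedom allowed). Note the degrees of freedom
#' here are \eqn{n^* - 1}, while the hypothesis test in
#' \code{\link{testCluster}} uses \eqn{n^*}.
#'
#' @param sigmaW Weighted standard deviation (\eqn{\ge 0}).
#' @param nStar Effective sample size, must exceed 1.
#' @param alpha Significance level (default 0.05).
#' @return The standard error.
#' @export
standardError <- function(sigmaW, nStar, alpha = 0.05) {
  if (nStar <= 1) stop("effective sample size must exceed 1")
  if (sigmaW < 0) stop("sigmaW must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qt(1 - alpha / 2, df = nStar - 1) * sigmaW / sqrt(nStar)
}

#' Weighted one-sample t-test of a cluster mean
#'
#' Tests \eqn{\mu^* = \mu_0} (default 0 = no copy-number difference) with
#' \eqn{t = \sqrt{n^*} (\mu^* - \mu_0)/\sigma_w} and two-sided p-value
#' \eqn{p = 2 \Pr(T_{n^*} \le -|t|)} on \eqn{n^*} degrees of freedom.
#'
#' Degenerate zero-dispersion clusters (all kept ratios identical) get
#' \eqn{t = 0, p = 1} when \eqn{\mu^* = \mu_0} and \eqn{t = \pm\infty,
#' p = 0} otherwise; the dispersion factor \eqn{\phi = 0} then forces
#' \eqn{Q = 0}, so such clusters are never called (flagged downstream).
#'
#' @param x Normalized log2 ratios of the kept subset.
#' @param w Positive weights.
#' @param mu0 Null mean (default 0).
#' @return A list with \code{tStat}, \code{pValue}, \code{muStar},
#'   \code{sigmaW2}, \code{nStar}.
#' @export
testCluster <- function(x, w, mu0 = 0) {
  muStar <- weightedMean(x, w)
  sigmaW2 <- weightedVariance(x, w, muStar)
  nStar <- effectiveN(w)
  sigmaW <- sqrt(sigmaW2)
  if (sigmaW == 0) {
    if (muStar == mu0) {
      t <- 0; p <- 1
    } else {
      t <- sign(muStar - mu0) * Inf; p <- 0
    }
  } else {
    t <- sqrt(nStar) * (muStar - mu0) / sigmaW
    p <- 2 * stats::pt(-abs(t), df = nStar)
  }
  list(tStat = t, pValue = p, muStar = muStar, sigmaW2 = sigmaW2,
       nStar = nStar)
}

#' Dispersion factor for the Q score
#'
#' \eqn{\phi = \sqrt{\sigma_w} \times (1 + |\mu^*|)}: penalizes
#' suspiciously low within-cluster dispersion (which inflates t) and
#' rewards large absolute effect sizes, removing the need for a separate
#' log2-ratio threshold. The radicand is the weighted standard deviation
#' \eqn{\sigma_w}, not the variance.
#'
#' @param sigmaW Weighted standard deviation (\eqn{\ge 0}).
#' @param muStar Weighted mean log2 ratio.
#' @return \eqn{\phi \ge 0}.
#' @export
dispersionFactor <- function(sigmaW, muStar) {
  if (any(sigmaW < 0)) stop("sigmaW must be non-negative")
  sqrt(sigmaW) * (1 + abs(muStar))
}

#' Dispersion-corrected significance score Q
#'
#' \eqn{Q = -10 \log_{10}(p) \times \phi}, a Phred-like score; calls
#' require \eqn{Q \ge 50} by default. p-values at or below the smallest
#' representable double are clamped to it (with a WARN log line), keeping
#' Q finite: Q is a ranking score, not an inferential quantity.
#'
#' @param p p-value in (0, 1]; non-positive values are clamped.
#' @param phi Dispersion factor (\eqn{\ge 0}).
#' @return The Q score (\eqn{\ge 0}).
#' @export
qualityScore <- function(p, phi) {
  if (any(phi < 0)) stop("phi must be non-negative")
  if (any(p > 1)) stop("p must not exceed 1")
  tooSmall <- p < .Machine$double.xmin
  if (any(tooSmall)) {
    .logWarn(sum(tooSmall),
             " p-value(s) at or below double precision; clamped for Q")
    p[tooSmall] <- .Machine$double.xmin
  }
  -10 * log10(p) * phi
}

#' Precision score P
#'
#' \eqn{P = -10 \ln(SE_{\mu^*})}: larger P means a tighter copy-number
#' estimate (P = 20 corresponds to SE \eqn{= e^{-2} \approx 0.135};
#' negative P is possible when SE exceeds 1). Undefined (NA) for SE
#' \eqn{\le 0}; reported as "." in VCF output.
#'
#' @param se Standard error of the weighted mean.
#' @return The P score, or NA for non-positive SE.
#' @export
precisionScore <- function(se) {
  out <- rep(NA_real_, length(se))
  ok <- is.finite(se) & se > 0
  out[ok] <- -10 * log(se[ok])
  out
}

#' Copy-number estimate with confidence bounds
#'
#' \eqn{N_S = N_C \times 2^{\mu^*}} with bounds
#' \eqn{N_C \times 2^{\mu^* \pm SE_{\mu^*}}}. \eqn{N_C} is the copy
#' number of the region in the control (2 for autosomes in a diploid
#' control, sex-dependent for chrX/chrY). \eqn{N_S} is deliberately left
#' real-valued: fractional estimates (e.g. 3.5) are meaningful under
#' mosaicism or impure samples and the gain/loss decision does not
#' require integers.
#'
#' @param muStar Weighted mean normalized log2 ratio.
#' @param se Standard error of \code{muStar} (\eqn{\ge 0}).
#' @param nControl Control copy number (integer \eqn{\ge 1}).
#' @return A list with \code{nSample}, \code{nMin}, \code{nMax}.
#' @export
copyNumberEstimate <- function(muStar, se, nControl) {
  if (nControl < 1) stop("control copy number must be >= 1")
  if (se < 0) stop("se must be non-negative")
  list(nSample = nControl * 2^muStar,
       nMin = nControl * 2^(muStar - se),
       nMax = nControl * 2^(muStar + se))
}

#' Iterative Shapiro-Wilk outlier pruning
#'
#' Per cluster, true outliers (primer-site variants, mapping loss,
#' aberrant PCR efficiency) are removed by iterating: (1) Shapiro-Wilk
#' normality test on the current subset's log2 ratios (unweighted); (2)
#' stop if its p-value exceeds \code{swAlpha}; (3) otherwise remove the
#' single element farthest from the \emph{weighted} mean \eqn{\mu^*} of
#' the current subset and repeat. At most \code{floor(n/3)} elements are
#' ever removed (n = original cluster size); if the test still rejects at
#' the cap, the cluster is flagged. Ties on the removal criterion go to
#' the smaller weight, then to the earlier genomic position, so pruning
#' is deterministic.
#'
#' @param x Normalized log2 ratios of a cluster (length \eqn{\ge 3}), in
#'   genomic order.
#' @param w Positive weights, same length.
#' @param swAlpha Shapiro-Wilk rejection level (default 0.05).
#' @return A list: \code{keep} (logical vector over \code{x}),
#'   \code{nRemoved}, \code{swPValue} (final subset's test p-value, NA if
#'   untestable), \code{capHit} (TRUE when pruning stopped at the cap
#'   with normality still rejected).
#' @export
removeOutliers <- function(x, w, swAlpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("Shapiro-Wilk pruning needs at least 3 values")
  if (length(w) != n) stop("x and w must have equal length")
  if (any(w <= 0)) stop("weights must be positive")
  cap <- floor(n / 3)
  keep <- rep(TRUE, n)
  removed <- 0L
  swP <- NA_real_
  capHit <- FALSE
  repeat {
    xs <- x[keep]
    if (length(xs) < 3) { capHit <- TRUE; break }
    swP <- .shapiroP(xs)
    if (is.na(swP) || swP > swAlpha) break
    if (removed >= cap) { capHit <- TRUE; break }
    mu <- weightedMean(xs, w[keep])
    d <- abs(x - mu)
    d[!keep] <- -Inf
    # farthest from mu*; ties -> smaller weight, then earlier position
    cand <- which(d == max(d))
    if (length(cand) > 1) cand <- cand[order(w[cand], cand)]
    keep[cand[1]] <- FALSE
    removed <- removed + 1L
  }
  list(keep = keep, nRemoved = removed, swPValue = swP, capHit = capHit)
}

# Shapiro-Wilk p-value; NA when the test cannot run (constant values --
# treated as trivially "normal enough" since zero dispersion is handled
# separately). The test is limited to 5000 values; larger clusters are
# tested on an evenly spaced subset.
.shapiroP <- function(x) {
  if (length(unique(x)) < 3 || diff(range(x)) < 1e-10) return(NA_real_)
  if (length(x) > 5000)
    x <- x[round(seq(1, length(x), length.out = 5000))]
  out <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  out
}
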