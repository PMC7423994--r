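## Negative-binomial differential expression: median-of-ratios size
## factors, QC filters, sample-level QC, and a self-contained NB Wald test
## with trend-shrunk method-of-moments dispersions, including the
## mid-parent-value contrast.

#' Median-of-ratios size factors
#'
#' Per sample, the median over loci (restricted to loci with a positive
#' geometric mean across samples) of count / locus-geometric-mean,
#' renormalised so the size factors have geometric mean 1. Accounts for
#' both sequencing depth and RNA composition. When no locus is positive in
#' all samples, falls back to total-count scaling with a warning.
#'
#' @param counts a count matrix or SummarizedExperiment, loci in rows.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' sizeFactorsMedianRatio(m)
#' @export
sizeFactorsMedianRatio <- function(counts) {
  m <- countMatrix(counts)
  logGeo <- rowMeans(log(m))
  use <- is.finite(logGeo)
  if (!any(use)) {
    warnf("no locus with all-positive counts: falling back to total-count scaling")
    sf <- colSums(m)
    if (any(sf <= 0)) stopf("a sample has zero total count")
  } else {
    sf <- apply(m[use, , drop = FALSE], 2, function(col)
      exp(median(log(col) - logGeo[use])))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

normalizeCounts <- function(counts, sizeFactors = NULL) {
  m <- countMatrix(counts)
  sf <- sizeFactors %||% sizeFactorsMedianRatio(m)
  list(norm = sweep(m, 2, sf, "/"), sf = sf)
}

#' Gene-level QC filter
#'
#' Removes loci with zero total count, loci whose mean normalized count is
#' below `minMeanNorm`, and extreme count outliers: with at least three
#' samples, a locus where any single normalized count exceeds
#' `outlierFold` times the locus' trimmed mean (trim 20%, floored at 1 to
#' keep the rule stable at low counts).
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param minMeanNorm minimum mean normalized count (default 1).
#' @param outlierFold leverage multiple for the outlier rule (default 10).
#' @param sizeFactors optional precomputed size factors.
#' @return list with `counts` (retained rows, same class as a matrix) and
#'   `log`, a `DataFrame` of removed loci and reasons.
#' @export
qcFilter <- function(counts, minMeanNorm = 1, outlierFold = 10,
                     sizeFactors = NULL) {
  m <- countMatrix(counts)
  nc <- normalizeCounts(m, sizeFactors)$norm
  reason <- rep(NA_character_, nrow(m))
  reason[rowSums(m) == 0] <- "zero total count"
  low <- is.na(reason) & rowMeans(nc) < minMeanNorm
  reason[low] <- sprintf("mean normalized count below %g", minMeanNorm)
  if (ncol(m) >= 3) {
    tm <- apply(nc, 1, mean, trim = 0.2)
    out <- is.na(reason) & apply(nc, 1, max) > outlierFold * pmax(tm, 1)
    reason[out] <- "extreme count outlier"
  }
  keep <- is.na(reason)
  list(counts = m[keep, , drop = FALSE],
       log = S4Vectors::DataFrame(locus_id = rownames(m)[!keep],
                                  reason = reason[!keep]))
}

#' Sample-level QC: PCA, hierarchical clustering, outlier flags
#'
#' PCA and average-linkage hierarchical clustering (Euclidean distance) on
#' log2 normalized counts. A sample is flagged when, at the merge where it
#' first joins a cluster, that cluster contains a sample from a different
#' group -- i.e. it failed to join its own group's cluster before any
#' other group's member.
#'
#' @param counts count matrix or SummarizedExperiment (>= 3 samples).
#' @param groups group label per sample.
#' @return list with `pca` (coordinates and variance explained), `hclust`
#'   (the dendrogram object) and `flagged` (character vector of outlier
#'   sample names).
#' @export
sampleQC <- function(counts, groups) {
  m <- countMatrix(counts)
  if (ncol(m) < 3) stopf("sample QC requires at least 3 samples")
  if (length(groups) != ncol(m)) stopf("one group label per sample required")
  ln <- log2(normalizeCounts(m)$norm + 1)
  pc <- prcomp(t(ln), center = TRUE, scale. = FALSE)
  hc <- hclust(dist(t(ln)), method = "average")
  flagged <- character()
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    side <- function(j) if (j < 0) -j else members[[j]]
    a <- side(hc$merge[i, 1])
    b <- side(hc$merge[i, 2])
    if (hc$merge[i, 1] < 0 && any(groups[b] != groups[a]))
      flagged <- c(flagged, colnames(m)[a])
    if (hc$merge[i, 2] < 0 && any(groups[a] != groups[b]))
      flagged <- c(flagged, colnames(m)[b])
    members[[i]] <- c(a, b)
  }
  list(pca = list(coords = pc$x,
                  varExplained = pc$sdev^2 / sum(pc$sdev^2)),
       hclust = hc, flagged = unique(flagged))
}

## ---- dispersion machinery -------------------------------------------------

## Method-of-moments dispersion per locus from normalized counts of one or
## more groups (list of column-index vectors). Returns raw (possibly
## negative) estimates plus the locus mean.
momDispersion <- function(norm, sf, groupCols) {
  num <- 0
  den <- 0
  mu <- 0
  wsum <- 0
  for (g in groupCols) {
    ng <- length(g)
    mg <- rowMeans(norm[, g, drop = FALSE])
    vg <- apply(norm[, g, drop = FALSE], 1, var)
    aInv <- mean(1 / sf[g])  # E Var(k/s) = mu/s + phi mu^2
    num <- num + (ng - 1) * (vg - mg * aInv)
    den <- den + (ng - 1) * mg^2
    mu <- mu + ng * mg
    wsum <- wsum + ng
  }
  list(phiRaw = ifelse(den > 0, num / den, NA_real_), mu = mu / wsum)
}

## Parametric mean-dispersion trend phi(mu) = a0 + a1/mu fitted by least
## squares with one outlier-trimming pass; coefficients clamped >= 0.
fitDispersionTrend <- function(mu, phiRaw) {
  ok <- is.finite(phiRaw) & is.finite(mu) & mu > 0
  if (sum(ok) < 10) {
    md <- max(median(phiRaw[ok], na.rm = TRUE), 1e-6)
    return(function(m) rep(md, length(m)))
  }
  fit1 <- lm(phiRaw[ok] ~ I(1 / mu[ok]))
  res <- residuals(fit1)
  keep <- abs(res) <= 3 * mad(res) + 1e-12
  fit <- lm(phiRaw[ok][keep] ~ I(1 / mu[ok][keep]))
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

shrunkDispersion <- function(norm, sf, groupCols, trendWeight) {
  mom <- momDispersion(norm, sf, groupCols)
  trend <- fitDispersionTrend(mom$mu, mom$phiRaw)
  phi <- trendWeight * trend(mom$mu) +
    (1 - trendWeight) * ifelse(is.finite(mom$phiRaw), mom$phiRaw,
                               trend(mom$mu))
  pmin(pmax(phi, 1e-8), 10)
}

## Variance of the normalized group mean under NB(mu, phi) counts.
groupMeanVar <- function(mu, phi, sf, cols) {
  ng <- length(cols)
  (mu * sum(1 / sf[cols]) / ng^2) + phi * mu^2 / ng
}

resolveColumns <- function(m, cols) {
  if (is.character(cols)) match(cols, colnames(m)) else as.integer(cols)
}

#' Negative-binomial Wald test between two sample groups
#'
#' Per locus: normalized group means; a per-locus method-of-moments
#' dispersion shrunk toward a fitted mean-dispersion trend (weighted
#' average with weight `trendWeight` on the trend); a Wald statistic on
#' the log2 fold change with a delta-method standard error; two-sided
#' normal p-values with Benjamini-Hochberg adjustment across tested loci.
#' Loci with zero counts in both groups are excluded.
#'
#' @param counts count matrix or SummarizedExperiment containing both
#'   groups' samples.
#' @param group1,group2 column names or indices of the two groups (each
#'   with >= 2 samples). `direction` is `up_in_first` when group 1 is
#'   higher.
#' @param sizeFactors optional precomputed size factors for all columns of
#'   `counts`; by default median-of-ratios factors are estimated from the
#'   union of the two groups.
#' @param alpha FDR threshold for the direction call (default 0.05).
#' @param trendWeight weight of the dispersion trend in the shrinkage
#'   (default 0.8; 0 = pure per-locus moments, 1 = pure trend).
#' @param contrast label stored in the result.
#' @return A `DataFrame`: `locus_id`, `contrast`, `base_mean`, `log2_fc`
#'   (display fold change with a +0.5 pseudocount on normalized means),
#'   `stat`, `p_value`, `fdr`, `direction`.
#' @export
nbTest <- function(counts, group1, group2, sizeFactors = NULL, alpha = 0.05,
                   trendWeight = 0.8, contrast = "group1:group2") {
  m <- countMatrix(counts)
  g1 <- resolveColumns(m, group1)
  g2 <- resolveColumns(m, group2)
  if (length(g1) < 2 || length(g2) < 2)
    stopf("each group needs at least 2 samples")
  sub <- m[, c(g1, g2), drop = FALSE]
  nz <- normalizeCounts(sub, if (!is.null(sizeFactors))
    sizeFactors[c(g1, g2)] else NULL)
  norm <- nz$norm
  sf <- nz$sf
  i1 <- seq_along(g1)
  i2 <- length(g1) + seq_along(g2)
  tested <- rowSums(sub) > 0
  norm <- norm[tested, , drop = FALSE]

  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  phi <- shrunkDispersion(norm, sf, list(i1, i2), trendWeight)

  ## floor a zero group mean at half a read in that group's library
  floor1 <- 0.5 / sum(sf[i1])
  floor2 <- 0.5 / sum(sf[i2])
  e1 <- pmax(m1, floor1)
  e2 <- pmax(m2, floor2)
  v1 <- groupMeanVar(e1, phi, sf, i1)
  v2 <- groupMeanVar(e2, phi, sf, i2)
  se <- sqrt(v1 / e1^2 + v2 / e2^2) / log(2)
  stat <- (log2(e1) - log2(e2)) / se
  p <- 2 * pnorm(-abs(stat))
  fdr <- bhAdjust(p)
  direction <- ifelse(fdr < alpha,
                      ifelse(stat > 0, "up_in_first", "up_in_second"),
                      "no_de")
  S4Vectors::DataFrame(
    locus_id = rownames(norm),
    contrast = contrast,
    base_mean = unname((m1 + m2) / 2),
    log2_fc = unname(log2((m1 + 0.5) / (m2 + 0.5))),
    stat = unname(stat), p_value = unname(p), fdr = unname(fdr),
    direction = factor(direction,
                       levels = c("up_in_first", "up_in_second", "no_de")))
}

#' Mid-parent-value contrast
#'
#' Tests, per locus, the null that the polyploid mean equals the
#' mid-parent value `(mu_A + mu_B) / 2` on the normalized scale, as a
#' linear contrast with a delta-method variance
#' `Var(m_M) + Var(m_A)/4 + Var(m_B)/4` (replicate-level variance is
#' preserved; no averaged pseudo-samples are constructed).
#'
#' @param counts count matrix or SummarizedExperiment with all samples.
#' @param polyploid,parentA,parentB column names/indices (each >= 2).
#' @param sizeFactors,alpha,trendWeight,contrast as in [nbTest()].
#' @return A `DataFrame` as in [nbTest()]; `direction` is `up_in_first`
#'   when the polyploid exceeds the MPV.
#' @export
mpvTest <- function(counts, polyploid, parentA, parentB, sizeFactors = NULL,
                    alpha = 0.05, trendWeight = 0.8, contrast = "M:MPV") {
  m <- countMatrix(counts)
  gM <- resolveColumns(m, polyploid)
  gA <- resolveColumns(m, parentA)
  gB <- resolveColumns(m, parentB)
  if (min(lengths(list(gM, gA, gB))) < 2)
    stopf("each group needs at least 2 samples")
  cols <- c(gM, gA, gB)
  sub <- m[, cols, drop = FALSE]
  nz <- normalizeCounts(sub, if (!is.null(sizeFactors))
    sizeFactors[cols] else NULL)
  norm <- nz$norm
  sf <- nz$sf
  iM <- seq_along(gM)
  iA <- length(gM) + seq_along(gA)
  iB <- length(gM) + length(gA) + seq_along(gB)
  tested <- rowSums(sub) > 0
  norm <- norm[tested, , drop = FALSE]

  mM <- rowMeans(norm[, iM, drop = FALSE])
  mA <- rowMeans(norm[, iA, drop = FALSE])
  mB <- rowMeans(norm[, iB, drop = FALSE])
  phi <- shrunkDispersion(norm, sf, list(iM, iA, iB), trendWeight)
  vM <- groupMeanVar(pmax(mM, 1e-8), phi, sf, iM)
  vA <- groupMeanVar(pmax(mA, 1e-8), phi, sf, iA)
  vB <- groupMeanVar(pmax(mB, 1e-8), phi, sf, iB)
  num <- mM - (mA + mB) / 2
  se <- sqrt(vM + vA / 4 + vB / 4)
  stat <- num / se
  p <- 2 * pnorm(-abs(stat))
  fdr <- bhAdjust(p)
  direction <- ifelse(fdr < alpha,
                      ifelse(stat > 0, "up_in_first", "up_in_second"),
                      "no_de")
  S4Vectors::DataFrame(
    locus_id = rownames(norm),
    contrast = contrast,
    base_mean = unname((mM + mA + mB) / 3),
    log2_fc = unname(log2((mM + 0.5) / ((mA + mB) / 2 + 0.5))),
    stat = unname(stat), p_value = unname(p), fdr = unname(fdr),
    direction = factor(direction,
                       levels = c("up_in_first", "up_in_second", "no_de")))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at
#' 1) via [stats::p.adjust()]. Values outside `[0, 1]` raise an error.
#'
#' @param p numeric vector of p-values.
#' @return vector of BH-adjusted values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
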