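## Poisson-Gamma homeolog-specific expression model.
##
## Per replicate i, reads from the two homeologs of a locus are
## x_A,i ~ Poisson(lambda_i * p) and x_B,i ~ Poisson(lambda_i * (1 - p)),
## with p = theta * (1 - qA) + (1 - theta) * qB and the replicate intensity
## lambda_i carrying a Gamma prior. Conditioning on the replicate total
## n_i = x_A,i + x_B,i integrates lambda_i out exactly:
## x_A,i | n_i ~ Binomial(n_i, p). With a Beta(a, b) prior on theta the
## posterior is evaluated on a uniform grid over [0, 1]; in the q = 0 limit
## it reduces to the conjugate Beta(a + sum x_A, b + sum x_B).

## Aggregate homeolog counts to per-locus sufficient statistics (SA, SB).
homeologTotals <- function(counts) {
  if (is(counts, "HomeologCounts")) {
    data.frame(locus_id = rownames(counts),
               SA = rowSums(countsA(counts)),
               SB = rowSums(countsB(counts)),
               stringsAsFactors = FALSE)
  } else {
    counts <- as.data.frame(counts)
    need <- c("locus", "count_A", "count_B")
    if (!all(need %in% names(counts)))
      stopf("long-format homeolog counts need columns: %s",
            paste(need, collapse = ", "))
    SA <- tapply(counts$count_A, counts$locus, sum)
    data.frame(locus_id = names(SA), SA = as.numeric(SA),
               SB = as.numeric(tapply(counts$count_B, counts$locus, sum)),
               stringsAsFactors = FALSE)
  }
}

## Grid quantile from node densities (trapezoid CDF, linear interpolation).
gridQuantiles <- function(theta, dens, probs) {
  h <- theta[2] - theta[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * h))
  cdf <- cdf / cdf[length(cdf)]
  vapply(probs, function(q) {
    k <- which(cdf >= q)[1]
    if (k == 1L) return(theta[1])
    d <- cdf[k] - cdf[k - 1]
    if (d <= 0) return(theta[k])
    theta[k - 1] + (q - cdf[k - 1]) / d * h
  }, numeric(1))
}

#' Posterior of the homeolog expression proportion theta
#'
#' Computes, per locus, the posterior of the proportion theta of total
#' expression contributed by the parent-A homeolog, correcting for read
#' misassignment at rates `qA`, `qB`, and classifies each locus as
#' `unbiased`, `biased_A`, or `biased_B` according to whether the
#' equal-tailed credible interval at `level` excludes 0.5.
#'
#' @param counts a [HomeologCounts-class] object, or a long-format data
#'   frame with columns `locus`, `replicate`, `count_A`, `count_B`.
#' @param qA,qB misassignment rates in `[0, 0.5)`; scalars or per-locus
#'   vectors aligned with the loci in `counts`.
#' @param priorA,priorB Beta prior parameters (flat `Beta(1, 1)` default).
#' @param gridPoints number of uniform grid nodes (>= 101; forced odd so
#'   composite Simpson quadrature applies).
#' @param level credible level defining the bias call (default 0.95).
#' @param minTotal loci with fewer total reads across replicates are
#'   excluded (prior-dominated calls) and recorded in the `excluded`
#'   attribute with a reason.
#' @param keepDensity store the full grid density matrix in
#'   `metadata(result)$density` (off by default to bound memory on large
#'   runs).
#' @return A `DataFrame` with `locus_id`, `total_A`, `total_B`,
#'   `theta_mean`, `ci_low`, `ci_high`, `bias_class`; excluded loci are in
#'   `metadata(result)$excluded`.
#' @examples
#' hc <- homeologCounts(matrix(c(10, 12, 9), 1), matrix(c(50, 48, 55), 1))
#' thetaPosterior(hc, qA = 0, qB = 0)
#' @export
thetaPosterior <- function(counts, qA = 0, qB = 0, priorA = 1, priorB = 1,
                           gridPoints = 2001L, level = 0.95, minTotal = 10L,
                           keepDensity = FALSE) {
  tot <- homeologTotals(counts)
  L <- nrow(tot)
  if (any(qA < 0 | qA >= 0.5) || any(qB < 0 | qB >= 0.5))
    stopf("misassignment rates must lie in [0, 0.5)")
  if (priorA <= 0 || priorB <= 0) stopf("Beta prior parameters must be > 0")
  gridPoints <- as.integer(gridPoints)
  if (gridPoints < 101L) stopf("gridPoints must be >= 101")
  if (gridPoints %% 2L == 0L) gridPoints <- gridPoints + 1L
  qA <- rep_len(qA, L)
  qB <- rep_len(qB, L)

  theta <- seq(0, 1, length.out = gridPoints)
  w <- simpsonWeights(gridPoints)
  logPrior <- xlogy(priorA - 1, theta) + xlogy(priorB - 1, 1 - theta)

  keep <- tot$SA + tot$SB >= minTotal
  reason <- ifelse(tot$SA + tot$SB == 0, "all counts zero",
                   sprintf("total count below %d", minTotal))
  excluded <- S4Vectors::DataFrame(locus_id = tot$locus_id[!keep],
                                   reason = reason[!keep])

  idx <- which(keep)
  n <- length(idx)
  thetaMean <- ciLow <- ciHigh <- numeric(n)
  densities <- if (keepDensity) matrix(NA_real_, gridPoints, n) else NULL
  for (k in seq_len(n)) {
    i <- idx[k]
    p <- theta * (1 - qA[i]) + (1 - theta) * qB[i]
    lp <- logPrior + xlogy(tot$SA[i], p) + xlogy(tot$SB[i], 1 - p)
    u <- exp(lp - max(lp))
    Z <- sum(w * u)
    dens <- u / Z
    if (keepDensity) densities[, k] <- dens
    thetaMean[k] <- sum(w * theta * dens)
    ci <- gridQuantiles(theta, dens, c((1 - level) / 2, 1 - (1 - level) / 2))
    ciLow[k] <- ci[1]
    ciHigh[k] <- ci[2]
  }
  out <- S4Vectors::DataFrame(
    locus_id = tot$locus_id[idx],
    total_A = tot$SA[idx], total_B = tot$SB[idx],
    theta_mean = thetaMean, ci_low = ciLow, ci_high = ciHigh,
    bias_class = classifyBias(thetaMean, ciLow, ciHigh))
  S4Vectors::metadata(out) <- list(
    excluded = excluded, theta_grid = theta, density = densities,
    level = level, prior = c(priorA, priorB))
  out
}

#' Three-way homeolog bias call from a credible interval
#'
#' `biased_A` iff the interval excludes 0.5 from above (posterior mass on
#' the parent-A side), `biased_B` iff it excludes 0.5 from below, else
#' `unbiased`.
#'
#' @param thetaMean posterior means (unused for the call itself but kept
#'   in the signature for clarity; the interval determines the class).
#' @param ciLow,ciHigh equal-tailed credible bounds.
#' @return factor with levels `unbiased`, `biased_A`, `biased_B`.
#' @export
classifyBias <- function(thetaMean, ciLow, ciHigh) {
  cls <- ifelse(ciLow > 0.5, "biased_A",
                ifelse(ciHigh < 0.5, "biased_B", "unbiased"))
  factor(cls, levels = biasLevels)
}

categoryTable <- local({
  tb <- expand.grid(parental_de = c("no_de", "A_higher", "B_higher"),
                    bias_class = biasLevels, stringsAsFactors = FALSE)
  key <- paste(tb$parental_de, tb$bias_class)
  cat <- c("no_de unbiased" = 1L, "A_higher biased_A" = 2L,
           "B_higher biased_B" = 3L, "A_higher unbiased" = 4L,
           "B_higher unbiased" = 5L, "no_de biased_A" = 6L,
           "no_de biased_B" = 7L, "A_higher biased_B" = 8L,
           "B_higher biased_A" = 9L)
  grp <- c("parental_legacy", "parental_legacy", "parental_legacy",
           "absence_of_bias", "absence_of_bias",
           "novel_bias", "novel_bias", "novel_bias", "novel_bias")
  data.frame(key = names(cat), category = unname(cat),
             group = grp, stringsAsFactors = FALSE)
})

#' Assign the nine homeolog-expression categories
#'
#' Combines the parental differential-expression call with the polyploid
#' homeolog bias class into the fixed nine-category scheme: categories 1-3
#' are parental legacy (the parental pattern is vertically transmitted),
#' 4-5 absence of bias (parents differ, homeologs do not), 6-9 novel bias
#' (bias toward the parent that did not show higher diploid expression, or
#' arising without parental differential expression).
#'
#' @param parentalDE character/factor per locus in
#'   `{A_higher, B_higher, no_de}`.
#' @param biasClass character/factor per locus in
#'   `{unbiased, biased_A, biased_B}`.
#' @param locusIds optional locus identifiers.
#' @return A `DataFrame` with `locus_id`, `category` (1-9) and `group`;
#'   loci with a missing call in either input are dropped and counted in
#'   `metadata(result)$n_skipped`.
#' @export
assignCategory <- function(parentalDE, biasClass, locusIds = NULL) {
  parentalDE <- as.character(parentalDE)
  biasClass <- as.character(biasClass)
  if (length(parentalDE) != length(biasClass))
    stopf("parentalDE and biasClass must have equal length")
  if (is.null(locusIds)) locusIds <- sprintf("locus%05d", seq_along(parentalDE))
  ok <- !is.na(parentalDE) & !is.na(biasClass)
  key <- paste(parentalDE[ok], biasClass[ok])
  m <- match(key, categoryTable$key)
  if (anyNA(m))
    stopf("unrecognised call combination: '%s'", key[which(is.na(m))[1]])
  out <- S4Vectors::DataFrame(
    locus_id = locusIds[ok],
    category = categoryTable$category[m],
    group = factor(categoryTable$group[m],
                   levels = c("parental_legacy", "absence_of_bias",
                              "novel_bias")))
  S4Vectors::metadata(out) <- list(n_skipped = sum(!ok))
  out
}

#' Compare homeolog bias calls between two polyploid forms
#'
#' Cross-tabulates the three-way bias classes of loci shared by two
#' reciprocally formed polyploid lineages and extracts the loci with
#' lineage-specific bias toward a form's maternal parent (biased toward
#' that parent in the form, unbiased in the other form).
#'
#' @param calls1,calls2 per-locus bias classes: named vectors/factors or
#'   `DataFrame`s with `locus_id` and `bias_class` (e.g. from
#'   [thetaPosterior()]).
#' @param maternal1,maternal2 the maternal parent (`"A"` or `"B"`) of each
#'   form.
#' @return A list with `table` (3x3 contingency, form 1 rows) and
#'   `maternalSpecific` (`DataFrame` of locus, form, bias class).
#' @export
compareForms <- function(calls1, calls2, maternal1, maternal2) {
  asNamed <- function(x) {
    if (is(x, "DataFrame") || is.data.frame(x))
      stats::setNames(as.character(x$bias_class), x$locus_id)
    else stats::setNames(as.character(x), names(x))
  }
  c1 <- asNamed(calls1)
  c2 <- asNamed(calls2)
  shared <- intersect(names(c1), names(c2))
  c1 <- factor(c1[shared], levels = biasLevels)
  c2 <- factor(c2[shared], levels = biasLevels)
  tab <- table(form1 = c1, form2 = c2)
  maternalClass <- function(parent) paste0("biased_", match.arg(parent, c("A", "B")))
  m1 <- shared[c1 == maternalClass(maternal1) & c2 == "unbiased"]
  m2 <- shared[c2 == maternalClass(maternal2) & c1 == "unbiased"]
  list(table = tab,
       maternalSpecific = S4Vectors::DataFrame(
         locus_id = c(m1, m2),
         form = rep(c("form1", "form2"), c(length(m1), length(m2))),
         bias_class = c(as.character(c1[match(m1, shared)]),
                        as.character(c2[match(m2, shared)]))))
}

#' Chi-square goodness-of-fit test of balanced bias (or dominance)
#'
#' One-degree-of-freedom goodness-of-fit of the observed split between the
#' two parental directions against equal expected counts,
#' `chi2 = sum (obs - exp)^2 / exp`.
#'
#' @param nA,nB loci counted toward each parent (`nA + nB >= 1`).
#' @return list with `statistic` and `p.value`.
#' @examples
#' biasBalanceTest(444, 545)
#' @export
biasBalanceTest <- function(nA, nB) {
  if (nA < 0 || nB < 0 || nA + nB < 1)
    stopf("need non-negative counts with nA + nB >= 1")
  e <- (nA + nB) / 2
  chi2 <- (nA - e)^2 / e + (nB - e)^2 / e
  list(statistic = chi2, p.value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' @rdname biasBalanceTest
#' @export
eldBalanceTest <- biasBalanceTest
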