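## Mapping-bias screen on diploid cross-mapping assignment counts, and
## misassignment-rate estimation feeding the homeolog posterior.

checkAssignmentCounts <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("locus_id", "aa", "ab", "bb", "ba")
  if (!all(need %in% names(counts)))
    stopf("assignment counts need columns: %s", paste(need, collapse = ", "))
  for (j in c("aa", "ab", "bb", "ba"))
    if (any(counts[[j]] < 0)) stopf("negative count in column '%s'", j)
  counts
}

#' Screen ortholog pairs for reference mapping bias
#'
#' Using diploid reads aligned against the joint parental reference, a
#' locus whose reads from one parent are predominantly assigned to the
#' other parent's transcript cannot distinguish homeologs and is excluded
#' from homeolog-specific expression analysis. "Predominantly" is
#' operationalised as a cross-assignment fraction above `crossThreshold`;
#' loci whose denominator is below `minReads` in either parent are called
#' `indeterminate` (ratio too unstable to label).
#'
#' @param counts data frame with columns `locus_id`, `aa` (parent-A reads
#'   assigned to the A reference), `ab` (parent-A reads assigned to the B
#'   reference), and the mirror counts `bb`, `ba`.
#' @param crossThreshold cross-assignment fraction above which a locus is
#'   `biased_mapping`; in (0, 1].
#' @param minReads minimum per-parent read total for a determinate call.
#' @return A `DataFrame` with `locus_id`, the two cross fractions, and
#'   `mapping` in `{unbiased_mapping, biased_mapping, indeterminate}`.
#' @examples
#' screenMappingBias(data.frame(locus_id = "L1", aa = 100, ab = 0,
#'                              bb = 100, ba = 0))
#' @export
screenMappingBias <- function(counts, crossThreshold = 0.5, minReads = 10) {
  if (crossThreshold <= 0 || crossThreshold > 1)
    stopf("crossThreshold must lie in (0, 1]")
  counts <- checkAssignmentCounts(counts)
  dA <- counts$aa + counts$ab
  dB <- counts$bb + counts$ba
  crossA <- ifelse(dA > 0, counts$ab / dA, NA_real_)
  crossB <- ifelse(dB > 0, counts$ba / dB, NA_real_)
  label <- ifelse(dA < minReads | dB < minReads, "indeterminate",
                  ifelse(crossA > crossThreshold | crossB > crossThreshold,
                         "biased_mapping", "unbiased_mapping"))
  S4Vectors::DataFrame(locus_id = counts$locus_id,
                       cross_A = crossA, cross_B = crossB,
                       mapping = factor(label,
                                        levels = c("unbiased_mapping",
                                                   "biased_mapping",
                                                   "indeterminate")))
}

#' Estimate homeolog read misassignment rates from diploid cross-mapping
#'
#' The misassignment rate qA is the fraction of parent-A diploid reads
#' assigned to the B reference, `qA = ab / (aa + ab)` (and symmetrically
#' for qB), optionally with pseudocount smoothing of each cell.
#'
#' @param counts assignment counts as in [screenMappingBias()]; one or
#'   more loci. Counts are summed over loci when `pooled = TRUE`, giving a
#'   single global estimate.
#' @param pseudocount added to every cell before forming the ratio
#'   (default 0.5; use 0 for the raw ratio).
#' @param pooled sum counts over loci before estimating (default `FALSE`).
#' @return A `DataFrame` with `locus_id` (or `"pooled"`), `qA`, `qB`.
#' @examples
#' estimateMisassignment(data.frame(locus_id = "L1", aa = 90, ab = 10,
#'                                  bb = 90, ba = 10), pseudocount = 0)
#' @export
estimateMisassignment <- function(counts, pseudocount = 0.5, pooled = FALSE) {
  counts <- checkAssignmentCounts(counts)
  if (pooled) {
    counts <- data.frame(locus_id = "pooled", aa = sum(counts$aa),
                         ab = sum(counts$ab), bb = sum(counts$bb),
                         ba = sum(counts$ba))
  }
  dA <- counts$aa + counts$ab
  dB <- counts$bb + counts$ba
  if (pseudocount == 0 && any(dA < 1 | dB < 1))
    stopf(paste("zero assignment total at locus '%s': use pseudocount",
                "smoothing or a global pooled estimate"),
          counts$locus_id[which(dA < 1 | dB < 1)[1]])
  qA <- (counts$ab + pseudocount) / (dA + 2 * pseudocount)
  qB <- (counts$ba + pseudocount) / (dB + 2 * pseudocount)
  S4Vectors::DataFrame(locus_id = counts$locus_id, qA = qA, qB = qB)
}
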