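## Shared fixtures and independent oracles used across the suite.

se_counts <- function(x) SummarizedExperiment::assay(x, "counts")

## A small default simulation reused by several files.
smallSim <- function(nLoci = 300, seed = 11, ...) {
  simulateCounts(simConfig(nLoci = nLoci, seed = seed, ...))
}

## Independent brute-force best-hit scan: for each query, scan every hit
## and keep the maximal bitscore (ties: minimal evalue, then smallest
## subject id); reciprocal pairs by exhaustive double loop.
bruteForceRBH <- function(ab, ba) {
  best <- function(hits) {
    hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
    out <- list()
    for (q in unique(hits$qseqid)) {
      h <- hits[hits$qseqid == q, , drop = FALSE]
      h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
      h <- h[h$evalue == min(h$evalue), , drop = FALSE]
      h <- h[order(h$sseqid), , drop = FALSE]
      out[[q]] <- h$sseqid[1]
    }
    out
  }
  bA <- best(ab)
  bB <- best(ba)
  pairs <- character(0)
  for (a in names(bA)) {
    b <- bA[[a]]
    if (!is.null(bB[[b]]) && bB[[b]] == a)
      pairs <- c(pairs, paste(a, b, sep = "|"))
  }
  sort(pairs)
}

pairKeys <- function(pairs) sort(paste(pairs$id_A, pairs$id_B, sep = "|"))

## Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
## probabilities not exceeding that of the observed table.
fisherEnumerate <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
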