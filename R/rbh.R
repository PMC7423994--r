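## Reciprocal-best-hit ortholog calling between two parental transcript sets.

blastCols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the standard 12-column order (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore); extra
#' columns are ignored. Malformed rows raise an error naming the line.
#'
#' @param path path to a tab-separated hit table without header.
#' @return data frame with the 12 standard columns.
#' @export
readBlastTab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), blastCols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad))
    stopf("malformed BLAST tabular row at line %d: expected >= 12 fields, got %d",
          bad[1], length(parts[[bad[1]]]))
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & !is.na(m[, j]))
    if (length(bad))
      stopf("malformed BLAST tabular row at line %d: non-numeric '%s' in column %s",
            bad[1], m[bad[1], j], blastCols[j])
    out[[blastCols[j]]] <- v
  }
  for (j in c("length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send"))
    out[[j]] <- as.integer(out[[j]])
  out
}

## Best hit per query: maximal bitscore, ties by minimal evalue, then
## lexicographically smallest subject id. Self-hits are ignored.
bestHits <- function(hits) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Identify reciprocal best hits between two transcript sets
#'
#' A pair (a, b) is retained iff b is a's best hit in the A-vs-B table and
#' a is b's best hit in the B-vs-A table. "Best" means maximal bitscore,
#' with ties broken by minimal E-value and then by the lexicographically
#' smallest subject id; hits of a transcript to itself are ignored, and a
#' query with no hits simply yields no pair.
#'
#' @param hitsAB,hitsBA data frames as returned by [readBlastTab()] (the
#'   columns `qseqid`, `sseqid`, `pident`, `length`, `evalue`, `bitscore`
#'   are used).
#' @return A `DataFrame` of ortholog pairs with supporting hit statistics
#'   from both directions (suffixes `_ab` for the A-as-query hit and `_ba`
#'   for the B-as-query hit).
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  ab <- bestHits(hitsAB)
  ba <- bestHits(hitsBA)
  empty <- S4Vectors::DataFrame(
    id_A = character(), id_B = character(),
    pident_ab = numeric(), length_ab = integer(), evalue_ab = numeric(),
    bitscore_ab = numeric(), pident_ba = numeric(), length_ba = integer(),
    evalue_ba = numeric(), bitscore_ba = numeric())
  if (!nrow(ab) || !nrow(ba)) return(empty)
  key_ab <- paste(ab$qseqid, ab$sseqid, sep = "\r")
  key_ba <- paste(ba$sseqid, ba$qseqid, sep = "\r")
  keep <- key_ab %in% key_ba
  if (!any(keep)) return(empty)
  ab <- ab[keep, , drop = FALSE]
  ba <- ba[match(paste(ab$qseqid, ab$sseqid, sep = "\r"), key_ba), ,
           drop = FALSE]
  out <- S4Vectors::DataFrame(
    id_A = ab$qseqid, id_B = ab$sseqid,
    pident_ab = ab$pident, length_ab = ab$length, evalue_ab = ab$evalue,
    bitscore_ab = ab$bitscore,
    pident_ba = ba$pident, length_ba = ba$length, evalue_ba = ba$evalue,
    bitscore_ba = ba$bitscore)
  out[order(out$id_A), ]
}

#' Filter ortholog pairs on similarity thresholds
#'
#' Retains pairs whose designated-direction hit satisfies E-value <=
#' `maxEvalue`, identity >= `minIdentity` and alignment length >=
#' `minLength` (all bounds inclusive). The default direction applies the
#' thresholds to the B-as-query hit, matching the convention of filtering
#' on the search that used the second parent's transcripts as query;
#' `direction = "both"` requires both hits to pass.
#'
#' @param pairs a `DataFrame` from [reciprocalBestHits()].
#' @param maxEvalue,minIdentity,minLength inclusive thresholds.
#' @param direction which hit the thresholds apply to: `"ba"` (default),
#'   `"ab"`, or `"both"`.
#' @return The retained subset of `pairs`.
#' @export
filterPairs <- function(pairs, maxEvalue = 1e-10, minIdentity = 80,
                        minLength = 200, direction = c("ba", "ab", "both")) {
  direction <- match.arg(direction)
  if (!nrow(pairs)) return(pairs)
  pass <- function(sfx) {
    pairs[[paste0("evalue_", sfx)]] <= maxEvalue &
      pairs[[paste0("pident_", sfx)]] >= minIdentity &
      pairs[[paste0("length_", sfx)]] >= minLength
  }
  keep <- switch(direction,
                 ba = pass("ba"),
                 ab = pass("ab"),
                 both = pass("ab") & pass("ba"))
  pairs[keep, , drop = FALSE]
}

#' Intersect RBH pairs with single-copy ortholog groups
#'
#' Retains the pairs present (as the same unordered id pair) both in the
#' RBH result and in an externally provided single-copy group table.
#'
#' @param pairs a `DataFrame` with columns `id_A`, `id_B`.
#' @param groups a two-column data frame/DataFrame mapping one A-id to one
#'   B-id per group; a duplicated id raises a validation error.
#' @return The subset of `pairs` shared with `groups`.
#' @export
intersectWithGroups <- function(pairs, groups) {
  g1 <- as.character(groups[[1]])
  g2 <- as.character(groups[[2]])
  if (anyDuplicated(g1) || anyDuplicated(g2))
    stopf("duplicate id in the single-copy group table")
  unorderedKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keep <- unorderedKey(pairs$id_A, pairs$id_B) %in% unorderedKey(g1, g2)
  pairs[keep, , drop = FALSE]
}
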