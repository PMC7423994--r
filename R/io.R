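## Tab-separated readers/writers for the pipeline's tabular interfaces.
## Counts: first column locus id, remaining columns samples, header row.
## Homeolog counts: long format (locus, replicate, count_A, count_B).
## Assignment counts: locus_id, aa, ab, bb, ba.

#' Read / write locus x sample count tables
#'
#' @param path TSV path; first column the locus id, remaining columns one
#'   per sample, with a header row of sample names.
#' @return `readCountsTSV`: an integer matrix with locus row names.
#' @export
readCountsTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric counts in %s", path)
  rownames(m) <- df[[1]]
  m
}

#' @rdname readCountsTSV
#' @param counts matrix or SummarizedExperiment to write.
#' @param idColumn name of the locus-id column in the header.
#' @export
writeCountsTSV <- function(counts, path, idColumn = "locus_id") {
  m <- countMatrix(counts)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write homeolog counts in long format
#'
#' @param path TSV with columns `locus`, `replicate`, `count_A`,
#'   `count_B`.
#' @return `readHomeologTSV`: a [HomeologCounts-class] object.
#' @export
readHomeologTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "replicate", "count_A", "count_B")
  if (!all(need %in% names(df)))
    stopf("homeolog TSV needs columns: %s", paste(need, collapse = ", "))
  loci <- unique(df$locus)
  reps <- sort(unique(df$replicate))
  shape <- function(col) {
    m <- matrix(0L, length(loci), length(reps),
                dimnames = list(loci, paste0("rep", reps)))
    m[cbind(match(df$locus, loci), match(df$replicate, reps))] <- df[[col]]
    m
  }
  homeologCounts(shape("count_A"), shape("count_B"), locusIds = loci)
}

#' @rdname readHomeologTSV
#' @param hc a [HomeologCounts-class] object to write.
#' @export
writeHomeologTSV <- function(hc, path) {
  a <- countsA(hc)
  b <- countsB(hc)
  df <- data.frame(
    locus = rep(rownames(a), each = ncol(a)),
    replicate = rep(seq_len(ncol(a)), nrow(a)),
    count_A = as.vector(t(a)),
    count_B = as.vector(t(b)), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write diploid cross-mapping assignment counts
#'
#' @param path TSV with columns `locus_id`, `aa`, `ab`, `bb`, `ba`.
#' @return `readAssignmentTSV`: a data frame of validated counts.
#' @export
readAssignmentTSV <- function(path) {
  checkAssignmentCounts(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readAssignmentTSV
#' @param counts assignment-count data frame to write.
#' @export
writeAssignmentTSV <- function(counts, path) {
  write.table(checkAssignmentCounts(counts), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' @param path two-column TSV (`gene_id`, `term_id`), header optional
#'   third column with term descriptions.
#' @return data frame with `gene_id`, `term_id` (and `description` if
#'   present).
#' @export
readTermMapTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "term_id")
  df
}

#' Write a simulation truth table
#'
#' @param truth the `truth` DataFrame from [simulateCounts()].
#' @param path output TSV path.
#' @export
writeTruthTSV <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
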