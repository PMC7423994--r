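## Total-expression pattern classification: additivity, expression level
## dominance (ELD), transgressive expression, with balance and cross-form
## statistics.

patternCallLevels <- c(patternLevels, "conflict")

## Decision table over direction triples (M vs A, M vs B, A vs B), each in
## {first_higher, second_higher, no_de}; "first" is M (or A in the AB
## contrast).
classifyPatternOne <- function(ma, mb, ab) {
  if (ma == "no_de" && mb == "no_de") return("no_change")
  if (ma == "no_de") {                       # M == A, M != B
    if (ab == "no_de") return("conflict")    # A == B yet M differs from B
    return("eld_A")
  }
  if (mb == "no_de") {
    if (ab == "no_de") return("conflict")
    return("eld_B")
  }
  if (ma == "first_higher" && mb == "first_higher") return("transgressive_up")
  if (ma == "second_higher" && mb == "second_higher")
    return("transgressive_down")
  ## opposite directions: M strictly between the parents -> additivity,
  ## provided the parental contrast is significant and consistent
  if (ma == "first_higher" && mb == "second_higher") {
    ## A < M < B requires B > A, i.e. AB = second_higher
    if (ab == "second_higher") return("additivity")
    return("conflict")
  }
  ## M < A and M > B: requires A > B
  if (ab == "first_higher") return("additivity")
  "conflict"
}

#' Classify the total-expression pattern of each locus
#'
#' Maps the three pairwise direction calls -- polyploid vs parent A,
#' polyploid vs parent B, parent A vs parent B -- onto the pattern
#' taxonomy: `no_change` (polyploid differs from neither parent),
#' `additivity` (parents differ and the polyploid sits strictly between
#' them), expression level dominance `eld_A`/`eld_B` (the polyploid
#' matches exactly one parent while the parents differ), transgressive up-
#' or down-regulation (the polyploid exceeds or falls below both parents),
#' and `conflict` for the logically inconsistent remainder (e.g. parents
#' equivalent yet the polyploid differs from exactly one of them).
#'
#' @param deMA,deMB,deAB direction vectors in
#'   `{first_higher, second_higher, no_de}` ("first" = the polyploid for
#'   the first two, parent A for the third), or `DataFrame`s from
#'   [nbTest()] with `locus_id` and `direction` (joined by locus).
#' @param locusIds optional identifiers when vectors are supplied.
#' @return A `DataFrame` with `locus_id`, the three calls, and `pattern`;
#'   loci missing any call are dropped and counted in
#'   `metadata(result)$n_skipped`.
#' @export
classifyPattern <- function(deMA, deMB, deAB, locusIds = NULL) {
  asCalls <- function(x) {
    v <- if (is(x, "DataFrame") || is.data.frame(x))
      stats::setNames(as.character(x$direction), x$locus_id)
    else stats::setNames(as.character(x), names(x) %||% locusIds)
    ## accept the DECall vocabulary as synonyms
    v[v == "up_in_first"] <- "first_higher"
    v[v == "up_in_second"] <- "second_higher"
    bad <- setdiff(unique(v), c("first_higher", "second_higher", "no_de", NA))
    if (length(bad)) stopf("unrecognised direction call: '%s'", bad[1])
    v
  }
  ma <- asCalls(deMA)
  mb <- asCalls(deMB)
  ab <- asCalls(deAB)
  if (is.null(names(ma)) || is.null(names(mb)) || is.null(names(ab))) {
    if (length(unique(lengths(list(ma, mb, ab)))) != 1L)
      stopf("unnamed direction vectors must have equal length")
    ids <- locusIds %||% sprintf("locus%05d", seq_along(ma))
    names(ma) <- names(mb) <- names(ab) <- ids
  }
  shared <- Reduce(intersect, list(names(ma), names(mb), names(ab)))
  nSkipped <- length(unique(c(names(ma), names(mb), names(ab)))) -
    length(shared)
  ma <- ma[shared]
  mb <- mb[shared]
  ab <- ab[shared]
  ok <- !(is.na(ma) | is.na(mb) | is.na(ab))
  nSkipped <- nSkipped + sum(!ok)
  pattern <- mapply(classifyPatternOne, ma[ok], mb[ok], ab[ok],
                    USE.NAMES = FALSE)
  out <- S4Vectors::DataFrame(
    locus_id = shared[ok],
    de_MA = ma[ok], de_MB = mb[ok], de_AB = ab[ok],
    pattern = factor(pattern, levels = patternCallLevels))
  S4Vectors::metadata(out) <- list(n_skipped = nSkipped)
  out
}

#' Summarise pattern calls
#'
#' Counts and percentages per pattern, plus the non-additive share
#' (expression level dominance + transgressive expression).
#'
#' @param calls a `DataFrame` from [classifyPattern()] or a vector of
#'   pattern labels.
#' @return list with `table` (`DataFrame` of pattern, n, percent),
#'   `n_total`, `n_nonadditive`, `percent_nonadditive`.
#' @export
summarizePatterns <- function(calls) {
  pat <- if (is(calls, "DataFrame") || is.data.frame(calls))
    calls$pattern else calls
  pat <- factor(as.character(pat), levels = patternCallLevels)
  if (!length(pat)) stopf("no pattern calls supplied")
  n <- table(pat)
  nonadd <- sum(n[c("eld_A", "eld_B", "transgressive_up",
                    "transgressive_down")])
  list(table = S4Vectors::DataFrame(pattern = names(n),
                                    n = as.integer(n),
                                    percent = 100 * as.numeric(n) / length(pat)),
       n_total = length(pat),
       n_nonadditive = as.integer(nonadd),
       percent_nonadditive = 100 * nonadd / length(pat))
}

#' Compare non-additive proportions between two forms
#'
#' Two-sided Fisher's exact test on the 2x2 table of non-additive vs
#' other loci in two polyploid forms.
#'
#' @param nonadd1,total1,nonadd2,total2 non-additive and total locus
#'   counts per form (`nonadd <= total`).
#' @return list with `odds_ratio` (conditional MLE) and `p.value`.
#' @export
nonadditiveComparison <- function(nonadd1, total1, nonadd2, total2) {
  if (nonadd1 > total1 || nonadd2 > total2 || min(nonadd1, nonadd2) < 0)
    stopf("need 0 <= nonadd <= total for both forms")
  tab <- matrix(c(nonadd1, total1 - nonadd1, nonadd2, total2 - nonadd2),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("a margin of the 2x2 table is zero; returning p = 1")
    return(list(odds_ratio = NA_real_, p.value = 1))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p.value = ft$p.value)
}

#' Link between-form differential expression to patterns and bias
#'
#' For every locus differentially expressed between the two polyploid
#' forms, reports its total-expression pattern and homeolog bias class in
#' each form, and tabulates the patterns shown in the lower-expressing
#' form (e.g. how many loci that are higher in one form are transgressively
#' down-regulated in the other).
#'
#' @param deForms a `DataFrame` from [nbTest()] contrasting form 1 (first)
#'   vs form 2.
#' @param patterns1,patterns2 pattern calls per form ([classifyPattern()]
#'   output or named vectors).
#' @param bias1,bias2 optional bias classes per form ([thetaPosterior()]
#'   output or named vectors).
#' @return list with `report` (per-DE-locus `DataFrame`) and `breakdown`
#'   (`DataFrame`: higher form, pattern in the lower-expressing form,
#'   count).
#' @export
crosslink <- function(deForms, patterns1, patterns2,
                      bias1 = NULL, bias2 = NULL) {
  asNamed <- function(x, col) {
    if (is.null(x)) return(NULL)
    if (is(x, "DataFrame") || is.data.frame(x))
      stats::setNames(as.character(x[[col]]), x$locus_id)
    else stats::setNames(as.character(x), names(x))
  }
  p1 <- asNamed(patterns1, "pattern")
  p2 <- asNamed(patterns2, "pattern")
  b1 <- asNamed(bias1, "bias_class")
  b2 <- asNamed(bias2, "bias_class")
  de <- deForms[deForms$direction != "no_de", , drop = FALSE]
  if (!nrow(de)) {
    return(list(report = S4Vectors::DataFrame(
      locus_id = character(), higher_form = character(),
      pattern_form1 = character(), pattern_form2 = character(),
      bias_form1 = character(), bias_form2 = character()),
      breakdown = S4Vectors::DataFrame(higher_form = character(),
                                       pattern_in_lower_form = character(),
                                       n = integer())))
  }
  id <- de$locus_id
  higher <- ifelse(de$direction == "up_in_first", "form1", "form2")
  rep <- S4Vectors::DataFrame(
    locus_id = id,
    higher_form = higher,
    pattern_form1 = unname(p1[id]),
    pattern_form2 = unname(p2[id]),
    bias_form1 = if (is.null(b1)) NA_character_ else unname(b1[id]),
    bias_form2 = if (is.null(b2)) NA_character_ else unname(b2[id]))
  lowerPattern <- ifelse(higher == "form1", unname(p2[id]), unname(p1[id]))
  tab <- table(higher_form = higher,
               pattern = factor(lowerPattern, levels = patternCallLevels),
               useNA = "ifany")
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0 | !is.na(df$pattern), , drop = FALSE]
  list(report = rep,
       breakdown = S4Vectors::DataFrame(
         higher_form = df$higher_form,
         pattern_in_lower_form = as.character(df$pattern),
         n = as.integer(df$Freq)))
}
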