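## Pipeline orchestration and publication-style summary tables.

#' Percentage table with one-decimal display rounding
#'
#' Converts per-class locus counts into percentages (`100 * count /
#' total`), reported both at full precision and rounded half-up to one
#' decimal for display; totals are preserved.
#'
#' @param classCounts named non-negative integer vector (zero total is an
#'   error).
#' @return A `DataFrame` with `class`, `n`, `percent`,
#'   `percent_display`.
#' @examples
#' summarizeCountsTable(c(unbiased = 3895, biased_A = 444, biased_B = 545))
#' @export
summarizeCountsTable <- function(classCounts) {
  if (any(classCounts < 0) || any(classCounts != round(classCounts)))
    stopf("class counts must be non-negative integers")
  total <- sum(classCounts)
  if (total == 0) stopf("zero total count")
  pct <- 100 * classCounts / total
  S4Vectors::DataFrame(class = names(classCounts) %||%
                         as.character(seq_along(classCounts)),
                       n = as.integer(classCounts),
                       percent = as.numeric(pct),
                       percent_display = roundHalfUp(as.numeric(pct), 1))
}

deSummary <- function(de) {
  n <- nrow(de)
  nUp1 <- sum(de$direction == "up_in_first")
  nUp2 <- sum(de$direction == "up_in_second")
  list(n_tested = n,
       n_de = nUp1 + nUp2,
       percent_de = 100 * (nUp1 + nUp2) / n,
       percent_up_in_first = 100 * nUp1 / n,
       percent_up_in_second = 100 * nUp2 / n)
}

formInput <- function(f) {
  stopifnot(is.list(f), !is.null(f$counts))
  f$maternal <- match.arg(f$maternal %||% "A", c("A", "B"))
  f
}

#' Run the full homeolog / non-additive expression pipeline
#'
#' Orchestrates, on in-memory objects, the stages downstream of ortholog
#' calling: the mapping-bias screen (when diploid assignment counts are
#' supplied), the homeolog theta posterior with misassignment correction,
#' differential expression for all pairwise contrasts plus the mid-parent
#' value, the nine-category homeolog scheme, total-expression pattern
#' classification with balance tests, the cross-form comparison and
#' crosslink breakdown, and optional term enrichment of transgressive
#' loci. Sections whose inputs are withheld are marked absent; every stage
#' records its locus attrition.
#'
#' @param parentA,parentB SummarizedExperiments (or matrices) of diploid
#'   parent counts sharing locus ids.
#' @param forms named list of one or two polyploid forms; each a list with
#'   `counts` (SummarizedExperiment/matrix), optional `homeolog`
#'   ([HomeologCounts-class]), and `maternal` (`"A"` or `"B"`).
#' @param assignmentCounts optional diploid cross-mapping counts (see
#'   [screenMappingBias()]); when supplied, biased-mapping loci are
#'   excluded from homeolog inference and pooled misassignment rates are
#'   estimated from the unbiased loci.
#' @param termMap optional gene-to-term annotation for enrichment of
#'   transgressive loci.
#' @param alpha FDR threshold for direction calls.
#' @param level credible level for homeolog bias calls.
#' @param minTotal minimum homeolog read total per locus.
#' @param gridPoints posterior grid size.
#' @param trendWeight dispersion-shrinkage trend weight (see [nbTest()]).
#' @param minMeanNorm QC filter threshold (see [qcFilter()]).
#' @param seed seed for the (enrichment) resampling stages.
#' @return A nested list (report bundle): `homeolog` (per-form class
#'   counts/percentages, categories, balance test), `crossForm` (3x3
#'   table and maternal-specific counts), `contrasts` (percent DE and
#'   directional splits per contrast), `patterns` (per-form proportions,
#'   ELD balance, non-additive comparison), `crosslink`, `enrichment`,
#'   `attrition`, and `settings`. Serialise with [writeReport()].
#' @export
runPipeline <- function(parentA, parentB, forms, assignmentCounts = NULL,
                        termMap = NULL, alpha = 0.05, level = 0.95,
                        minTotal = 10L, gridPoints = 2001L,
                        trendWeight = 0.8, minMeanNorm = 1, seed = 1L) {
  forms <- lapply(forms, formInput)
  if (is.null(names(forms)))
    names(forms) <- paste0("form", seq_along(forms))
  cA <- countMatrix(parentA)
  cB <- countMatrix(parentB)
  shared <- intersect(rownames(cA), rownames(cB))
  attrition <- list()
  report <- list(settings = list(alpha = alpha, level = level,
                                 minTotal = minTotal,
                                 gridPoints = gridPoints,
                                 trendWeight = trendWeight,
                                 minMeanNorm = minMeanNorm, seed = seed,
                                 forms = lapply(forms, `[[`, "maternal")))

  ## ---- mapping-bias screen ----
  qA <- 0
  qB <- 0
  eligible <- NULL  # NULL = no screen supplied, all loci eligible
  if (!is.null(assignmentCounts)) {
    screen <- screenMappingBias(assignmentCounts)
    eligible <- screen$locus_id[screen$mapping == "unbiased_mapping"]
    qPooled <- estimateMisassignment(
      as.data.frame(assignmentCounts)[
        assignmentCounts$locus_id %in% eligible, , drop = FALSE],
      pooled = TRUE)
    qA <- qPooled$qA
    qB <- qPooled$qB
    attrition$mapping_screen <- list(
      input = nrow(screen),
      kept = length(eligible),
      removed = nrow(screen) - length(eligible))
    report$mappingScreen <- list(
      counts = as.list(table(screen$mapping)),
      qA = qA, qB = qB)
  }

  ## ---- homeolog-specific expression per form ----
  report$homeolog <- list()
  biasCalls <- list()
  for (nm in names(forms)) {
    hc <- forms[[nm]]$homeolog
    if (is.null(hc)) {
      report$homeolog[[nm]] <- list(absent = TRUE)
      next
    }
    if (!is.null(eligible)) hc <- hc[rownames(hc) %in% eligible, ]
    post <- thetaPosterior(hc, qA = qA, qB = qB, gridPoints = gridPoints,
                           level = level, minTotal = minTotal)
    biasCalls[[nm]] <- post
    cls <- table(post$bias_class)
    bal <- if (cls[["biased_A"]] + cls[["biased_B"]] >= 1)
      biasBalanceTest(cls[["biased_A"]], cls[["biased_B"]])
    else list(statistic = NA_real_, p.value = NA_real_)
    attrition[[paste0("homeolog_", nm)]] <- list(
      input = nrow(hc),
      kept = nrow(post),
      removed = nrow(S4Vectors::metadata(post)$excluded))
    report$homeolog[[nm]] <- list(
      classTable = as.data.frame(summarizeCountsTable(
        stats::setNames(as.integer(cls), names(cls)))),
      balance = bal)
  }

  ## ---- differential expression contrasts ----
  deResults <- list()
  runDE <- function(m1, m2, label) {
    joint <- cbind(m1, m2)
    qc <- qcFilter(joint, minMeanNorm = minMeanNorm)
    de <- nbTest(qc$counts, seq_len(ncol(m1)),
                 ncol(m1) + seq_len(ncol(m2)), alpha = alpha,
                 trendWeight = trendWeight, contrast = label)
    attrition[[paste0("de_", label)]] <<- list(
      input = nrow(joint), kept = nrow(de),
      removed = nrow(joint) - nrow(de))
    de
  }
  cA <- cA[shared, , drop = FALSE]
  cB <- cB[shared, , drop = FALSE]
  deResults[["A:B"]] <- runDE(cA, cB, "A:B")
  for (nm in names(forms)) {
    cM <- countMatrix(forms[[nm]]$counts)
    common <- intersect(rownames(cM), shared)
    cM <- cM[common, , drop = FALSE]
    deResults[[paste0(nm, ":A")]] <-
      runDE(cM, cA[common, , drop = FALSE], paste0(nm, ":A"))
    deResults[[paste0(nm, ":B")]] <-
      runDE(cM, cB[common, , drop = FALSE], paste0(nm, ":B"))
    joint <- cbind(cM, cA[common, , drop = FALSE], cB[common, , drop = FALSE])
    qc <- qcFilter(joint, minMeanNorm = minMeanNorm)
    deResults[[paste0(nm, ":MPV")]] <- mpvTest(
      qc$counts, seq_len(ncol(cM)), ncol(cM) + seq_len(ncol(cA)),
      ncol(cM) + ncol(cA) + seq_len(ncol(cB)), alpha = alpha,
      trendWeight = trendWeight, contrast = paste0(nm, ":MPV"))
  }
  if (length(forms) == 2L) {
    m1 <- countMatrix(forms[[1]]$counts)
    m2 <- countMatrix(forms[[2]]$counts)
    common <- intersect(rownames(m1), rownames(m2))
    lab <- paste(names(forms), collapse = ":")
    deResults[[lab]] <- runDE(m1[common, , drop = FALSE],
                              m2[common, , drop = FALSE], lab)
  }
  report$contrasts <- lapply(deResults, deSummary)

  ## ---- nine-category scheme per form ----
  parentalDir <- stats::setNames(
    as.character(deResults[["A:B"]]$direction), deResults[["A:B"]]$locus_id)
  parentalDE <- ifelse(parentalDir == "up_in_first", "A_higher",
                       ifelse(parentalDir == "up_in_second", "B_higher",
                              "no_de"))
  names(parentalDE) <- names(parentalDir)
  for (nm in names(biasCalls)) {
    post <- biasCalls[[nm]]
    common <- intersect(post$locus_id, names(parentalDE))
    cats <- assignCategory(parentalDE[common],
                           post$bias_class[match(common, post$locus_id)],
                           locusIds = common)
    report$homeolog[[nm]]$categories <- list(
      byCategory = as.list(table(factor(cats$category, levels = 1:9))),
      byGroup = as.data.frame(summarizeCountsTable(
        stats::setNames(as.integer(table(cats$group)),
                        levels(cats$group)))))
  }

  ## ---- cross-form comparison ----
  if (length(biasCalls) == 2L) {
    cf <- compareForms(biasCalls[[1]], biasCalls[[2]],
                       forms[[names(biasCalls)[1]]]$maternal,
                       forms[[names(biasCalls)[2]]]$maternal)
    report$crossForm <- list(
      table = as.data.frame(cf$table),
      n_maternal_specific = nrow(cf$maternalSpecific),
      maternal_specific_by_form = as.list(table(cf$maternalSpecific$form)))
  }

  ## ---- total-expression patterns per form ----
  patternCalls <- list()
  for (nm in names(forms)) {
    pat <- classifyPattern(deResults[[paste0(nm, ":A")]],
                           deResults[[paste0(nm, ":B")]],
                           deResults[["A:B"]])
    patternCalls[[nm]] <- pat
    sm <- summarizePatterns(pat)
    nEld <- table(pat$pattern)[c("eld_A", "eld_B")]
    report$patterns[[nm]] <- list(
      table = as.data.frame(sm$table),
      n_total = sm$n_total,
      n_nonadditive = sm$n_nonadditive,
      percent_nonadditive = sm$percent_nonadditive,
      eld_balance = if (sum(nEld) >= 1)
        eldBalanceTest(nEld[["eld_A"]], nEld[["eld_B"]])
      else list(statistic = NA_real_, p.value = NA_real_),
      n_conflict = sum(pat$pattern == "conflict"))
  }
  if (length(forms) == 2L) {
    s1 <- summarizePatterns(patternCalls[[1]])
    s2 <- summarizePatterns(patternCalls[[2]])
    report$patterns$nonadditiveComparison <- nonadditiveComparison(
      s1$n_nonadditive, s1$n_total, s2$n_nonadditive, s2$n_total)
    lab <- paste(names(forms), collapse = ":")
    cl <- crosslink(deResults[[lab]], patternCalls[[1]], patternCalls[[2]],
                    if (length(biasCalls) == 2L) biasCalls[[1]],
                    if (length(biasCalls) == 2L) biasCalls[[2]])
    report$crosslink <- list(
      n_de_between_forms = nrow(cl$report),
      breakdown = as.data.frame(cl$breakdown))
  }

  ## ---- enrichment of transgressive loci ----
  if (!is.null(termMap)) {
    report$enrichment <- list()
    for (nm in names(patternCalls)) {
      pat <- patternCalls[[nm]]
      bg <- pat$locus_id
      for (dirn in c("transgressive_up", "transgressive_down")) {
        tg <- pat$locus_id[pat$pattern == dirn]
        if (!length(tg)) next
        en <- termEnrichment(tg, bg, termMap, seed = seed)
        report$enrichment[[paste(nm, dirn, sep = ".")]] <-
          as.data.frame(head(en, 20))
      }
    }
  }

  report$attrition <- attrition
  report
}

#' Serialise a pipeline report to JSON
#'
#' @param report the list returned by [runPipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
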