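#' Simulation configuration for the synthetic allopolyploid study design
#'
#' A `SimConfig` holds every knob of the Gamma-Poisson (negative binomial)
#' generator that emulates the two-diploid-parents / one-allopolyploid
#' inflorescence RNA-seq design: three replicates per group by default,
#' log-normal baseline expression, per-locus parental log2 fold changes,
#' per-locus homeolog proportions theta, polyploid totals following an
#' assigned total-expression pattern, and symmetric read misassignment
#' between homeologs at rates qA and qB.
#'
#' @slot nLoci number of simulated loci.
#' @slot repsPerGroup biological replicates per group (>= 2; default 3).
#' @slot meanLogExpression location (natural-log scale) of baseline means.
#' @slot sdLogExpression scale of the log-normal baseline distribution.
#' @slot dispersion negative-binomial dispersion phi, Var = mu + phi * mu^2
#'   (phi = 0 gives Poisson counts).
#' @slot depthFactors per-sample positive library-size multipliers, ordered
#'   parent A replicates, parent B replicates, polyploid replicates; length
#'   1 (recycled) or 3 * repsPerGroup.
#' @slot fracParentalDE fraction of pattern-unconstrained loci given a
#'   parental log2 fold change of +/- parentalLfcMagnitude.
#' @slot parentalLfcMagnitude magnitude (log2) of simulated parental fold
#'   changes; also the transgressive excess beyond the extreme parent.
#' @slot fracBiasedTheta fraction of loci with a biased homeolog proportion.
#' @slot thetaBiasedRange interval inside (0,1), not containing 0.5, from
#'   which biased theta values are drawn (mirrored at random onto 1 - range).
#' @slot patternFractions named fractions over the six total-expression
#'   patterns (no_change, additivity, eld_A, eld_B, transgressive_up,
#'   transgressive_down); must sum to 1.
#' @slot misassignQA,misassignQB read misassignment rates in [0, 0.5): the
#'   probability that a read from the A (resp. B) homeolog is attributed to
#'   the other homeolog.
#' @slot seed integer seed driving all stochastic draws.
#'
#' @seealso [simConfig()], [simulateCounts()], [simulateHitTable()]
#' @export
setClass("SimConfig",
  representation(
    nLoci = "integer",
    repsPerGroup = "integer",
    meanLogExpression = "numeric",
    sdLogExpression = "numeric",
    dispersion = "numeric",
    depthFactors = "numeric",
    fracParentalDE = "numeric",
    parentalLfcMagnitude = "numeric",
    fracBiasedTheta = "numeric",
    thetaBiasedRange = "numeric",
    patternFractions = "numeric",
    misassignQA = "numeric",
    misassignQB = "numeric",
    seed = "integer"
  )
)

patternLevels <- c("no_change", "additivity", "eld_A", "eld_B",
                   "transgressive_up", "transgressive_down")

biasLevels <- c("unbiased", "biased_A", "biased_B")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be a positive integer")
  if (object@repsPerGroup < 2L) msg <- c(msg, "repsPerGroup must be >= 2")
  if (object@sdLogExpression <= 0) msg <- c(msg, "sdLogExpression must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@depthFactors <= 0)) msg <- c(msg, "depthFactors must be > 0")
  nd <- length(object@depthFactors)
  if (!nd %in% c(1L, 3L * object@repsPerGroup))
    msg <- c(msg, "depthFactors must have length 1 or 3 * repsPerGroup")
  for (f in c("fracParentalDE", "fracBiasedTheta")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
  }
  if (object@parentalLfcMagnitude <= 0)
    msg <- c(msg, "parentalLfcMagnitude must be > 0")
  r <- object@thetaBiasedRange
  if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1 ||
      (r[1] <= 0.5 && r[2] >= 0.5))
    msg <- c(msg, "thetaBiasedRange must be an interval within (0,1) excluding 0.5")
  pf <- object@patternFractions
  if (!identical(sort(names(pf)), sort(patternLevels)))
    msg <- c(msg, sprintf("patternFractions must be named: %s",
                          paste(patternLevels, collapse = ", ")))
  else {
    if (any(pf < 0)) msg <- c(msg, "patternFractions must be non-negative")
    if (abs(sum(pf) - 1) > 1e-9)
      msg <- c(msg, "patternFractions must sum to 1 (tolerance 1e-9)")
  }
  for (f in c("misassignQA", "misassignQB")) {
    v <- slot(object, f)
    if (v < 0 || v >= 0.5) msg <- c(msg, sprintf("%s must lie in [0, 0.5)", f))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the emulated study: three replicates per group, a mean
#' locus depth of about 100 reads (log-normal with meanlog = log(100),
#' sdlog = 1), moderate biological dispersion (phi = 0.05), 20% of loci with
#' biased homeolog proportions drawn from (0.65, 0.90) or its mirror image,
#' four-fold parental differences where the assigned pattern requires them,
#' and 2% symmetric read misassignment.
#'
#' @param nLoci number of loci to simulate.
#' @param repsPerGroup replicates per group.
#' @param meanLogExpression,sdLogExpression log-normal baseline parameters.
#' @param dispersion NB dispersion phi.
#' @param depthFactors per-sample depth multipliers (length 1 or
#'   `3 * repsPerGroup`).
#' @param fracParentalDE fraction of pattern-unconstrained loci with parental
#'   differential expression.
#' @param parentalLfcMagnitude parental log2 fold-change magnitude.
#' @param fracBiasedTheta fraction of loci with biased theta.
#' @param thetaBiasedRange interval for biased theta (see [SimConfig-class]).
#' @param patternFractions named fractions over the six patterns.
#' @param misassignQA,misassignQB homeolog read misassignment rates.
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nLoci = 100, seed = 7)
#' cfg
#' @export
simConfig <- function(nLoci,
                      repsPerGroup = 3L,
                      meanLogExpression = log(100),
                      sdLogExpression = 1,
                      dispersion = 0.05,
                      depthFactors = 1,
                      fracParentalDE = 0.2,
                      parentalLfcMagnitude = 2,
                      fracBiasedTheta = 0.2,
                      thetaBiasedRange = c(0.65, 0.90),
                      patternFractions = c(no_change = 0.5, additivity = 0.1,
                                           eld_A = 0.1, eld_B = 0.1,
                                           transgressive_up = 0.1,
                                           transgressive_down = 0.1),
                      misassignQA = 0.02,
                      misassignQB = 0.02,
                      seed = 1L) {
  new("SimConfig",
      nLoci = as.integer(nLoci),
      repsPerGroup = as.integer(repsPerGroup),
      meanLogExpression = meanLogExpression,
      sdLogExpression = sdLogExpression,
      dispersion = dispersion,
      depthFactors = as.numeric(depthFactors),
      fracParentalDE = fracParentalDE,
      parentalLfcMagnitude = parentalLfcMagnitude,
      fracBiasedTheta = fracBiasedTheta,
      thetaBiasedRange = thetaBiasedRange,
      patternFractions = patternFractions[patternLevels],
      misassignQA = misassignQA,
      misassignQB = misassignQB,
      seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nLoci, "loci x", object@repsPerGroup,
      "replicates/group\n")
  cat("  baseline: lognormal(meanlog=", format(object@meanLogExpression,
      digits = 4), ", sdlog=", object@sdLogExpression,
      "), NB dispersion phi=", object@dispersion, "\n", sep = "")
  cat("  biased theta fraction:", object@fracBiasedTheta, "in (",
      paste(object@thetaBiasedRange, collapse = ", "), ") or mirror\n")
  cat("  misassignment qA =", object@misassignQA, ", qB =",
      object@misassignQB, "; seed =", object@seed, "\n")
  invisible(object)
})

#' Homeolog-resolved read counts in the polyploid
#'
#' `HomeologCounts` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with two integer assays, `countsA` and `countsB`: for every locus (row)
#' and polyploid replicate (column), the reads assigned to the parent-A and
#' parent-B homeolog respectively.
#'
#' @seealso [homeologCounts()], [countsA()], [countsB()], [thetaPosterior()]
#' @export
#' @import SummarizedExperiment
setClass("HomeologCounts", contains = "SummarizedExperiment")

setValidity("HomeologCounts", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("countsA", "countsB") %in% an))
    return("assays 'countsA' and 'countsB' are required")
  for (a in c("countsA", "countsB")) {
    m <- SummarizedExperiment::assay(object, a)
    if (any(m < 0)) msg <- c(msg, sprintf("%s contains negative counts", a))
    if (any(m != round(m))) msg <- c(msg, sprintf("%s is not integer", a))
  }
  if (ncol(object) < 1L) msg <- c(msg, "at least one replicate is required")
  if (length(msg)) msg else TRUE
})

#' Construct a HomeologCounts object
#'
#' @param countsA,countsB non-negative integer matrices (loci x replicates)
#'   of reads assigned to the A and B homeolog; dimensions must agree.
#' @param locusIds optional row names; defaults to rownames of `countsA`.
#' @return A validated [HomeologCounts-class] object.
#' @examples
#' hc <- homeologCounts(matrix(5:10, 3), matrix(1:6, 3))
#' countsA(hc)
#' @export
homeologCounts <- function(countsA, countsB, locusIds = rownames(countsA)) {
  countsA <- as.matrix(countsA)
  countsB <- as.matrix(countsB)
  if (!identical(dim(countsA), dim(countsB)))
    stopf("countsA and countsB must have identical dimensions")
  if (is.null(locusIds)) locusIds <- sprintf("locus%05d", seq_len(nrow(countsA)))
  dimnames(countsA) <- list(locusIds, sprintf("rep%d", seq_len(ncol(countsA))))
  dimnames(countsB) <- dimnames(countsA)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(countsA = countsA, countsB = countsB),
    colData = S4Vectors::DataFrame(replicate = seq_len(ncol(countsA)),
                                   row.names = colnames(countsA)))
  new("HomeologCounts", se)
}

#' @rdname homeologCounts
#' @param x a `HomeologCounts` object
#' @export
setGeneric("countsA", function(x) standardGeneric("countsA"))

#' @rdname homeologCounts
#' @export
setGeneric("countsB", function(x) standardGeneric("countsB"))

#' @rdname homeologCounts
#' @export
setMethod("countsA", "HomeologCounts",
          function(x) SummarizedExperiment::assay(x, "countsA"))

#' @rdname homeologCounts
#' @export
setMethod("countsB", "HomeologCounts",
          function(x) SummarizedExperiment::assay(x, "countsB"))

#' @describeIn homeologCounts compact display
#' @param object a `HomeologCounts`
#' @export
setMethod("show", "HomeologCounts", function(object) {
  cat("HomeologCounts:", nrow(object), "loci x", ncol(object),
      "polyploid replicates\n")
  tot <- sum(countsA(object)) + sum(countsB(object))
  cat("  total reads:", tot, "; overall A fraction:",
      format(sum(countsA(object)) / max(tot, 1), digits = 4), "\n")
  invisible(object)
})

#' Assemble a count SummarizedExperiment with sample metadata
#'
#' Thin constructor used throughout the package for locus x sample integer
#' count tables of one group (a diploid parent or a polyploid form).
#'
#' @param counts non-negative integer matrix, loci in rows.
#' @param species species/group label recorded in `colData`.
#' @param form optional polyploid form label (e.g. `"short"`, `"long"`).
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assay `"counts"`.
#' @export
countExperiment <- function(counts, species, form = NA_character_) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("locus%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s_rep%d", species, seq_len(ncol(counts)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(species = rep(species, ncol(counts)),
                                   form = rep(form, ncol(counts)),
                                   replicate = seq_len(ncol(counts)),
                                   row.names = colnames(counts)))
}

## Accept a SummarizedExperiment or bare matrix wherever counts are expected.
countMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}
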