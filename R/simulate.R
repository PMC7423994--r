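## synthetic data: Gamma-Poisson counts with known per-locus ground truth.

## NB draw supporting the phi -> 0 Poisson limit.
rnbinomPhi <- function(n, mu, phi) {
  if (phi <= 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate diploid and polyploid count data with ground truth
#'
#' Draws Gamma-Poisson (negative binomial) counts for the two diploid
#' parents and the allopolyploid under the configured study design, splits
#' each polyploid total into homeolog-assigned reads through the
#' misassignment mixture `p = theta * (1 - qA) + (1 - theta) * qB`, and
#' returns a per-locus truth table for parameter-recovery benchmarking.
#'
#' Each locus is assigned one of six total-expression patterns; the pattern
#' constrains the parental contrast (a `no_change` locus has equal parental
#' means; `additivity` and expression-level-dominance loci require a
#' parental fold change; transgressive loci receive one with probability
#' `fracParentalDE`). Polyploid means follow the pattern definition:
#' mid-parent for additivity, one parent's mean for dominance, and
#' `parentalLfcMagnitude` log2 units beyond the extreme parent for
#' transgressive loci.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `parentA`, `parentB`, `polyploid`
#'   (SummarizedExperiments of counts), `homeolog` (a
#'   [HomeologCounts-class] whose per-replicate totals equal the polyploid
#'   counts), and `truth` (a `DataFrame` with `locus_id`, `baseline_mean`,
#'   `mu_A`, `mu_B`, `mu_M`, `true_parental_lfc`, `true_theta`,
#'   `true_bias_class`, `true_pattern`).
#' @examples
#' sim <- simulateCounts(simConfig(nLoci = 50, seed = 1))
#' head(sim$truth)
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    L <- config@nLoci
    r <- config@repsPerGroup
    locus <- sprintf("locus%05d", seq_len(L))
    depth <- rep(config@depthFactors, length.out = 3L * r)
    dA <- depth[seq_len(r)]
    dB <- depth[r + seq_len(r)]
    dM <- depth[2L * r + seq_len(r)]

    base <- rlnorm(L, config@meanLogExpression, config@sdLogExpression)
    pattern <- sample(patternLevels, L, replace = TRUE,
                      prob = config@patternFractions)

    lfc <- numeric(L)
    sgn <- sample(c(-1, 1), L, replace = TRUE)
    must <- pattern %in% c("additivity", "eld_A", "eld_B")
    lfc[must] <- sgn[must] * config@parentalLfcMagnitude
    optional <- pattern %in% c("transgressive_up", "transgressive_down")
    lfc[optional] <- sgn[optional] * config@parentalLfcMagnitude *
      rbinom(sum(optional), 1L, config@fracParentalDE)

    muA <- base * 2^(lfc / 2)
    muB <- base * 2^(-lfc / 2)
    mag <- config@parentalLfcMagnitude
    muM <- base
    muM[pattern == "additivity"] <- ((muA + muB) / 2)[pattern == "additivity"]
    muM[pattern == "eld_A"] <- muA[pattern == "eld_A"]
    muM[pattern == "eld_B"] <- muB[pattern == "eld_B"]
    up <- pattern == "transgressive_up"
    muM[up] <- pmax(muA, muB)[up] * 2^mag
    dn <- pattern == "transgressive_down"
    muM[dn] <- pmin(muA, muB)[dn] * 2^(-mag)

    biased <- runif(L) < config@fracBiasedTheta
    theta <- rep(0.5, L)
    towardA <- runif(L) < 0.5
    u <- runif(L, config@thetaBiasedRange[1], config@thetaBiasedRange[2])
    if (config@thetaBiasedRange[1] < 0.5) u <- 1 - u  # canonicalise to > 0.5
    theta[biased & towardA] <- u[biased & towardA]
    theta[biased & !towardA] <- 1 - u[biased & !towardA]
    biasClass <- ifelse(!biased, "unbiased",
                        ifelse(theta > 0.5, "biased_A", "biased_B"))

    phi <- config@dispersion
    drawGroup <- function(mu, d) {
      m <- matrix(rnbinomPhi(L * length(d), mu = outer(mu, d), phi = phi),
                  nrow = L)
      storage.mode(m) <- "integer"
      rownames(m) <- locus
      m
    }
    cA <- drawGroup(muA, dA)
    cB <- drawGroup(muB, dB)
    cM <- drawGroup(muM, dM)

    p <- theta * (1 - config@misassignQA) + (1 - theta) * config@misassignQB
    xA <- matrix(rbinom(L * r, size = as.vector(cM), prob = rep(p, r)),
                 nrow = L)
    storage.mode(xA) <- "integer"
    xB <- cM - xA

    truth <- S4Vectors::DataFrame(
      locus_id = locus,
      baseline_mean = base,
      mu_A = muA, mu_B = muB, mu_M = muM,
      true_parental_lfc = lfc,
      true_theta = theta,
      true_bias_class = factor(biasClass, levels = biasLevels),
      true_pattern = factor(pattern, levels = patternLevels))

    list(parentA = countExperiment(cA, "parentA"),
         parentB = countExperiment(cB, "parentB"),
         polyploid = countExperiment(cM, "polyploid"),
         homeolog = homeologCounts(xA, xB, locusIds = locus),
         truth = truth)
  })
}

#' Simulate reciprocal BLAST-style hit tables with a known ortholog list
#'
#' Builds tabular similarity hits between two synthetic transcript sets in
#' which each true ortholog pair is the reciprocal best hit, optionally
#' decorated with decoy hits whose identity and alignment length violate
#' the high-confidence filters, and with a configurable fraction of
#' parent-A transcripts lacking any counterpart.
#'
#' @param config a [SimConfig-class]; `nLoci` transcripts per set and
#'   `seed` are used.
#' @param decoyFrac expected decoy hits per transcript (decoys score below
#'   every true hit: bitscore < 100, identity in 40-70%, length < 200 bp).
#' @param unpairedFrac fraction of parent-A transcripts with no ortholog
#'   (they receive only decoy hits, if any).
#' @return A list with `ab` and `ba` (data frames in BLAST outfmt-6 column
#'   order) and `truth` (data frame of the true `id_A`, `id_B` pairs).
#' @examples
#' ht <- simulateHitTable(simConfig(nLoci = 20, seed = 3), decoyFrac = 0.5)
#' nrow(ht$truth)
#' @export
simulateHitTable <- function(config, decoyFrac = 0.3, unpairedFrac = 0) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed + 1L, {
    L <- config@nLoci
    idA <- sprintf("A_%05d", seq_len(L))
    idB <- sprintf("B_%05d", seq_len(L))
    nUnpaired <- floor(unpairedFrac * L)
    paired <- seq_len(L) > nUnpaired
    nP <- sum(paired)

    hitRow <- function(q, s, pid, len, ev, bs) {
      data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
                 mismatch = round(len * (1 - pid / 100)), gapopen = 0L,
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
    }

    len <- round(runif(nP, 300, 2000))
    pid <- runif(nP, 85, 99.5)
    bs <- round(len * runif(nP, 1.2, 1.8), 1)
    ev <- 10^runif(nP, -180, -30)
    ab <- hitRow(idA[paired], idB[paired], pid, len, ev, bs)
    ba <- hitRow(idB[paired], idA[paired], pid, len, ev, bs)

    nDecoy <- round(decoyFrac * L)
    if (nDecoy > 0) {
      dq <- sample(L, nDecoy, replace = TRUE)
      ds <- sample(L, nDecoy, replace = TRUE)
      off <- (ds == dq)  # decoy must not duplicate the true pairing
      ds[off] <- (ds[off] %% L) + 1L
      dlen <- round(runif(nDecoy, 50, 190))
      dpid <- runif(nDecoy, 40, 70)
      dbs <- round(runif(nDecoy, 30, 95), 1)
      dev <- 10^runif(nDecoy, -9, -1)
      half <- seq_len(nDecoy) <= nDecoy / 2
      ab <- rbind(ab, hitRow(idA[dq[half]], idB[ds[half]], dpid[half],
                             dlen[half], dev[half], dbs[half]))
      ba <- rbind(ba, hitRow(idB[dq[!half]], idA[ds[!half]], dpid[!half],
                             dlen[!half], dev[!half], dbs[!half]))
    }
    list(ab = ab, ba = ba,
         truth = data.frame(id_A = idA[paired], id_B = idB[paired],
                            stringsAsFactors = FALSE))
  })
}
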