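test_that("identical configuration and seed give bit-identical output", {
  cfg <- simConfig(nLoci = 120, seed = 42)
  s1 <- simulateCounts(cfg)
  s2 <- simulateCounts(cfg)
  expect_identical(se_counts(s1$parentA), se_counts(s2$parentA))
  expect_identical(se_counts(s1$polyploid), se_counts(s2$polyploid))
  expect_identical(countsA(s1$homeolog), countsA(s2$homeolog))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  h1 <- simulateHitTable(cfg)
  h2 <- simulateHitTable(cfg)
  expect_identical(h1, h2)
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(10, misassignQA = 0.6), "0.5")
  expect_error(simConfig(10, thetaBiasedRange = c(0.4, 0.6)), "0.5")
  expect_error(simConfig(10, repsPerGroup = 1), "repsPerGroup")
  expect_error(simConfig(10, patternFractions = c(
    no_change = 0.6, additivity = 0.1, eld_A = 0.1, eld_B = 0.1,
    transgressive_up = 0.1, transgressive_down = 0.05)), "sum to 1")
})

test_that("counts follow negative-binomial moments", {
  ## near-constant baseline so all loci share one (mu, phi)
  cfg <- simConfig(nLoci = 5000, seed = 3, sdLogExpression = 1e-6,
                   fracParentalDE = 0, fracBiasedTheta = 0,
                   patternFractions = c(no_change = 1, additivity = 0,
                                        eld_A = 0, eld_B = 0,
                                        transgressive_up = 0,
                                        transgressive_down = 0))
  x <- as.vector(se_counts(simulateCounts(cfg)$parentA))
  mu <- 100
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu + 0.05 * mu^2, tolerance = 0.1)
})

test_that("poisson limit and unbiased theta give a symmetric homeolog split", {
  cfg <- simConfig(nLoci = 2000, seed = 5, dispersion = 0,
                   meanLogExpression = log(500), sdLogExpression = 1e-6,
                   fracBiasedTheta = 0, misassignQA = 0, misassignQB = 0,
                   fracParentalDE = 0,
                   patternFractions = c(no_change = 1, additivity = 0,
                                        eld_A = 0, eld_B = 0,
                                        transgressive_up = 0,
                                        transgressive_down = 0))
  sim <- simulateCounts(cfg)
  nA <- sum(countsA(sim$homeolog))
  n <- nA + sum(countsB(sim$homeolog))
  se <- sqrt(0.25 / n)
  expect_lt(abs(nA / n - 0.5), 3 * se)
})

test_that("homeolog assignment fraction matches the misassignment mixture", {
  ## all theta = 0.5, asymmetric q: expected A fraction
  ## p = 0.5 (1 - qA) + 0.5 qB
  cfg <- simConfig(nLoci = 2000, seed = 6, fracBiasedTheta = 0,
                   misassignQA = 0.10, misassignQB = 0.02,
                   meanLogExpression = log(200), fracParentalDE = 0,
                   patternFractions = c(no_change = 1, additivity = 0,
                                        eld_A = 0, eld_B = 0,
                                        transgressive_up = 0,
                                        transgressive_down = 0))
  sim <- simulateCounts(cfg)
  nA <- sum(countsA(sim$homeolog))
  n <- nA + sum(countsB(sim$homeolog))
  p <- 0.5 * 0.90 + 0.5 * 0.02
  expect_lt(abs(nA / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("truth-table composition matches the configured fractions", {
  cfg <- simConfig(nLoci = 10000, seed = 7, fracBiasedTheta = 0.2)
  truth <- simulateCounts(cfg)$truth
  ## binomial oracle: biased-locus count within 3 sqrt(n p (1-p)) of n p
  nBiased <- sum(truth$true_bias_class != "unbiased")
  expect_lt(abs(nBiased - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
  ## bias class consistent with theta
  expect_true(all(truth$true_theta[truth$true_bias_class == "unbiased"] == 0.5))
  expect_true(all(truth$true_theta[truth$true_bias_class == "biased_A"] > 0.5))
  expect_true(all(truth$true_theta[truth$true_bias_class == "biased_B"] < 0.5))
  biased <- abs(truth$true_theta - 0.5) > 0
  expect_true(all(abs(truth$true_theta[biased] - 0.5) >= 0.15 - 1e-12))
  ## pattern proportions within binomial error of their fractions
  tab <- table(truth$true_pattern)
  for (p in names(tab)) {
    f <- simConfig(10)@patternFractions[[p]]
    expect_lt(abs(tab[[p]] - 10000 * f), 4 * sqrt(10000 * f * (1 - f)))
  }
})

test_that("pattern means respect their definitions", {
  truth <- smallSim(500, seed = 8)$truth
  mid <- (truth$mu_A + truth$mu_B) / 2
  add <- truth$true_pattern == "additivity"
  expect_equal(truth$mu_M[add], mid[add])
  up <- truth$true_pattern == "transgressive_up"
  expect_true(all(truth$mu_M[up] > pmax(truth$mu_A, truth$mu_B)[up]))
  dn <- truth$true_pattern == "transgressive_down"
  expect_true(all(truth$mu_M[dn] < pmin(truth$mu_A, truth$mu_B)[dn]))
  eldA <- truth$true_pattern == "eld_A"
  expect_equal(truth$mu_M[eldA], truth$mu_A[eldA])
})

test_that("hit tables embed the truth as reciprocal best hits", {
  cfg <- simConfig(nLoci = 40, seed = 9)
  ## no decoys: RBH recovers every pair
  ht <- simulateHitTable(cfg, decoyFrac = 0)
  rbh <- reciprocalBestHits(ht$ab, ht$ba)
  expect_identical(pairKeys(rbh), pairKeys(ht$truth))
  ## decoys (identity ~50%, short) never displace the true best hit
  ht2 <- simulateHitTable(cfg, decoyFrac = 2)
  rbh2 <- reciprocalBestHits(ht2$ab, ht2$ba)
  expect_identical(pairKeys(rbh2), pairKeys(ht2$truth))
  expect_identical(pairKeys(rbh2), bruteForceRBH(ht2$ab, ht2$ba))
  ## unpaired parent-A transcripts are absent from the truth list
  ht3 <- simulateHitTable(cfg, decoyFrac = 0.5, unpairedFrac = 0.25)
  expect_equal(nrow(ht3$truth), 30)
  expect_false(any(sprintf("A_%05d", 1:10) %in% ht3$truth$id_A))
})

test_that("tabular writers round-trip", {
  sim <- smallSim(25, seed = 10)
  d <- withr::local_tempdir()
  writeCountsTSV(sim$parentA, file.path(d, "a.tsv"))
  expect_identical(readCountsTSV(file.path(d, "a.tsv")),
                   se_counts(sim$parentA))
  writeHomeologTSV(sim$homeolog, file.path(d, "h.tsv"))
  hc <- readHomeologTSV(file.path(d, "h.tsv"))
  expect_equal(unname(countsA(hc)), unname(countsA(sim$homeolog)))
  expect_equal(rownames(hc), rownames(sim$homeolog))
  writeTruthTSV(sim$truth, file.path(d, "t.tsv"))
  tt <- read.delim(file.path(d, "t.tsv"))
  expect_equal(tt$true_theta, sim$truth$true_theta)
})
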