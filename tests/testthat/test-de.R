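test_that("median-of-ratios size factors match closed forms", {
  m <- cbind(s1 = c(10, 20, 30, 40), s2 = c(10, 20, 30, 40))
  expect_equal(unname(sizeFactorsMedianRatio(m)), c(1, 1))
  ## sample 2 at exactly twice sample 1: factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(s1 = c(10, 20, 30, 40), s2 = c(20, 40, 60, 80))
  expect_equal(unname(sizeFactorsMedianRatio(m2)), c(1 / sqrt(2), sqrt(2)))
  ## geometric mean of the factors is 1
  set.seed(41)
  m3 <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6)
  expect_equal(exp(mean(log(sizeFactorsMedianRatio(m3)))), 1)
})

test_that("size factors agree with the DESeq2 estimator up to rescaling", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(3000, mu = 80, size = 5), ncol = 6)
  m[, 4:6] <- m[, 4:6] * 3L
  ours <- sizeFactorsMedianRatio(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("degenerate matrices fall back to total-count scaling", {
  ## no locus positive in every sample
  m <- cbind(s1 = c(5L, 0L), s2 = c(0L, 10L))
  expect_warning(sf <- sizeFactorsMedianRatio(m), "total-count")
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("the QC filter removes zero, low and outlier loci", {
  m <- rbind(zero = c(0, 0, 0, 0, 0, 0),
             low = c(1, 0, 0, 1, 0, 0),
             outlier = c(20, 22, 2000, 21, 19, 23),
             uniform = c(50, 50, 50, 50, 50, 50),
             ok = c(30, 45, 38, 41, 29, 35))
  colnames(m) <- paste0("s", 1:6)
  qc <- qcFilter(m)
  expect_setequal(rownames(qc$counts), c("uniform", "ok"))
  expect_match(qc$log$reason[qc$log$locus_id == "zero"], "zero")
  expect_match(qc$log$reason[qc$log$locus_id == "outlier"], "outlier")
  ## attrition: kept + removed = input
  expect_equal(nrow(qc$counts) + nrow(qc$log), nrow(m))
})

test_that("sample QC flags a corrupted replicate and spares clean groups", {
  set.seed(43)
  mu <- rlnorm(400, log(100), 1)
  ## group 2 shares depth but has a per-locus profile shift, so the
  ## difference survives normalization
  mu2 <- mu * 2^rnorm(400, 0, 0.8)
  clean <- function(m) matrix(rnbinom(400 * 3, mu = rep(m, 3), size = 20),
                              ncol = 3)
  g1 <- clean(mu)
  g2 <- clean(mu2)
  corrupted <- matrix(rnbinom(400, mu = sample(mu), size = 20), ncol = 1)
  m <- cbind(g1, corrupted, g2)
  colnames(m) <- c(paste0("g1_", 1:3), "g1_bad", paste0("g2_", 1:3))
  rownames(m) <- paste0("L", 1:400)
  qc <- sampleQC(m, groups = c("g1", "g1", "g1", "g1", "g2", "g2", "g2"))
  expect_true("g1_bad" %in% qc$flagged)
  expect_false(any(c(paste0("g1_", 1:3), paste0("g2_", 1:3)) %in% qc$flagged))
  ## two clean groups: no flags, groups separate on PC1
  m2 <- cbind(g1, g2)
  colnames(m2) <- c(paste0("g1_", 1:3), paste0("g2_", 1:3))
  rownames(m2) <- paste0("L", 1:400)
  qc2 <- sampleQC(m2, groups = rep(c("g1", "g2"), each = 3))
  expect_length(qc2$flagged, 0)
  pc1 <- qc2$pca$coords[, 1]
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) || min(pc1[1:3]) > max(pc1[4:6]))
  expect_error(sampleQC(m[, 1:2], groups = c("a", "b")), "3 samples")
})

test_that("equal groups give zero fold change and no calls", {
  m <- matrix(rep(c(40, 50, 60, 40, 50, 60), each = 1), nrow = 1)
  m <- rbind(m, m * 2, m * 3)
  rownames(m) <- paste0("L", 1:3)
  de <- nbTest(m, 1:3, 4:6)
  expect_equal(de$log2_fc, rep(0, 3))
  expect_equal(as.character(de$direction), rep("no_de", 3))
  expect_error(nbTest(m, 1, 2:3), "at least 2")
})

test_that("large true fold changes are detected with high power", {
  cfg <- simConfig(nLoci = 800, seed = 44, fracBiasedTheta = 0,
                   fracParentalDE = 1, meanLogExpression = log(200),
                   sdLogExpression = 0.3,
                   patternFractions = c(no_change = 0, additivity = 1,
                                        eld_A = 0, eld_B = 0,
                                        transgressive_up = 0,
                                        transgressive_down = 0))
  sim <- simulateCounts(cfg)
  m <- cbind(se_counts(sim$parentA), se_counts(sim$parentB))
  de <- nbTest(qcFilter(m)$counts, 1:3, 4:6)
  expect_gt(mean(de$direction != "no_de"), 0.8)
  ## direction agrees with the simulated sign
  tr <- sim$truth[match(de$locus_id, sim$truth$locus_id), ]
  called <- de$direction != "no_de"
  expect_gt(mean(sign(de$log2_fc[called]) ==
                 sign(tr$true_parental_lfc[called])), 0.99)
})

test_that("the MPV statistic is centred for additive loci and rejects dominance", {
  ## polyploid exactly at the mid-parent value, all groups equal
  m <- matrix(rnbinom(200 * 9, mu = 100, size = 20), ncol = 9)
  rownames(m) <- paste0("L", 1:200)
  set.seed(45)
  mp <- mpvTest(m, 1:3, 4:6, 7:9)
  expect_lt(abs(mean(mp$stat)), 0.2)
  ## dominance subset (mu_M = mu_A = 2 mu_B) against a mostly-null
  ## background so normalization stays anchored
  set.seed(46)
  mu <- rlnorm(300, log(300), 0.5)
  muB <- mu
  muB[1:40] <- mu[1:40] / 4
  draw <- function(mus) matrix(rnbinom(300 * 3, mu = rep(mus, 3), size = 100),
                               ncol = 3)
  m2 <- cbind(draw(mu), draw(mu), draw(muB))
  rownames(m2) <- paste0("L", 1:300)
  mp2 <- mpvTest(m2, 1:3, 4:6, 7:9)
  expect_gt(mean(mp2$direction[1:40] == "up_in_first"), 0.9)
  expect_lt(mean(mp2$direction[41:300] != "no_de"), 0.1)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  ## order invariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  o <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p)[o], bhAdjust(p[o]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("scaling one sample only rescales its size factor", {
  set.seed(47)
  m <- matrix(rnbinom(2000 * 6, mu = 500, size = 1 / 0.05), ncol = 6)
  rownames(m) <- paste0("L", 1:2000)
  m2 <- m
  m2[, 1] <- m2[, 1] * 4L
  sf1 <- sizeFactorsMedianRatio(m)
  sf2 <- sizeFactorsMedianRatio(m2)
  expect_equal(sf2[1] / sf1[1] / (sf2[2] / sf1[2]), 4, tolerance = 0.02)
  ## test statistics are nearly invariant at high depth
  de1 <- nbTest(m, 1:3, 4:6)
  de2 <- nbTest(m2, 1:3, 4:6)
  expect_gt(cor(de1$stat, de2$stat), 0.98)
})
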