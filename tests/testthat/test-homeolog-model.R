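hcOne <- function(xA, xB) {
  homeologCounts(matrix(xA, 1), matrix(xB, 1), locusIds = "L1")
}

test_that("grid posterior reduces to the conjugate Beta form when q = 0", {
  cases <- list(c(5, 0), c(31, 153), c(20, 20), c(3, 7), c(60, 12))
  for (cs in cases) {
    post <- thetaPosterior(hcOne(cs[1], cs[2]), qA = 0, qB = 0,
                           minTotal = 1, keepDensity = TRUE)
    md <- S4Vectors::metadata(post)
    ref <- dbeta(md$theta_grid, 1 + cs[1], 1 + cs[2])
    sel <- ref > 1e-12
    relErr <- abs(md$density[sel, 1] - ref[sel]) / ref[sel]
    expect_lt(max(relErr), 1e-8)
    expect_equal(post$theta_mean, (1 + cs[1]) / (2 + sum(cs)),
                 tolerance = 1e-10)
    ## credible bounds agree with the Beta quantiles
    expect_equal(post$ci_low, qbeta(0.025, 1 + cs[1], 1 + cs[2]),
                 tolerance = 1e-4)
    expect_equal(post$ci_high, qbeta(0.975, 1 + cs[1], 1 + cs[2]),
                 tolerance = 1e-4)
  }
})

test_that("symmetric counts give a posterior mean of exactly 0.5", {
  post <- thetaPosterior(hcOne(c(12, 10, 8), c(10, 8, 12)))
  expect_equal(post$theta_mean, 0.5)
  expect_equal(as.character(post$bias_class), "unbiased")
})

test_that("a single replicate 5 vs 0 matches Beta(6, 1)", {
  post <- thetaPosterior(hcOne(5, 0), minTotal = 1)
  expect_equal(post$theta_mean, 6 / 7, tolerance = 1e-9)
})

test_that("strongly B-shifted counts are called biased_B (Beta CDF oracle)", {
  post <- thetaPosterior(hcOne(c(10, 12, 9), c(50, 48, 55)), keepDensity = TRUE)
  ## oracle: posterior is Beta(1+31, 1+153); mass below 0.5
  expect_gt(pbeta(0.5, 32, 154), 0.999)
  md <- S4Vectors::metadata(post)
  h <- md$theta_grid[2]
  below <- md$theta_grid < 0.5
  massBelow <- sum(md$density[below, 1]) * h
  expect_gt(massBelow, 0.999)
  expect_equal(as.character(post$bias_class), "biased_B")
})

test_that("misassignment shifts the posterior toward 0.5", {
  ## observed A fraction 0.7; with qA = qB = 0.2 the de-mixed theta is
  ## (p - qB) / (1 - qA - qB) = (0.7 - 0.2) / 0.6 = 0.833
  postQ <- thetaPosterior(hcOne(700, 300), qA = 0.2, qB = 0.2)
  post0 <- thetaPosterior(hcOne(700, 300))
  expect_gt(postQ$theta_mean, post0$theta_mean)
  expect_equal(postQ$theta_mean, (0.7 - 0.2) / 0.6, tolerance = 0.05)
})

test_that("grid posterior agrees with a 10x finer grid when q > 0", {
  set.seed(17)
  for (i in 1:20) {
    xA <- rpois(3, runif(1, 3, 40))
    xB <- rpois(3, runif(1, 3, 40))
    if (sum(xA) + sum(xB) < 1) next
    qA <- runif(1, 0, 0.2)
    qB <- runif(1, 0, 0.2)
    p1 <- thetaPosterior(hcOne(xA, xB), qA, qB, gridPoints = 2001,
                         minTotal = 1)
    p2 <- thetaPosterior(hcOne(xA, xB), qA, qB, gridPoints = 20001,
                         minTotal = 1)
    expect_lt(abs(p1$theta_mean - p2$theta_mean), 1e-4)
  }
})

test_that("label exchange maps theta to 1 - theta and swaps classes", {
  xA <- c(40, 35, 50)
  xB <- c(10, 12, 9)
  p1 <- thetaPosterior(hcOne(xA, xB), qA = 0.05, qB = 0.02)
  p2 <- thetaPosterior(hcOne(xB, xA), qA = 0.02, qB = 0.05)
  expect_equal(p1$theta_mean, 1 - p2$theta_mean, tolerance = 1e-9)
  expect_equal(p1$ci_low, 1 - p2$ci_high, tolerance = 1e-6)
  expect_identical(as.character(p1$bias_class), "biased_A")
  expect_identical(as.character(p2$bias_class), "biased_B")
})

test_that("the posterior mean is monotone in the A total", {
  means <- vapply(c(10, 20, 40, 80), function(xa)
    thetaPosterior(hcOne(xa, 30))$theta_mean, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("low-count and all-zero loci are excluded with a reason", {
  hc <- homeologCounts(matrix(c(0, 3, 50), 3), matrix(c(0, 2, 60), 3),
                       locusIds = c("zero", "low", "ok"))
  post <- thetaPosterior(hc)
  expect_identical(post$locus_id, "ok")
  excl <- S4Vectors::metadata(post)$excluded
  expect_setequal(excl$locus_id, c("zero", "low"))
  expect_match(excl$reason[excl$locus_id == "zero"], "zero")
})

test_that("interval position determines the three-way bias call", {
  expect_equal(as.character(classifyBias(0.5, 0.48, 0.53)), "unbiased")
  expect_equal(as.character(classifyBias(0.55, 0.51, 0.60)), "biased_A")
  expect_equal(as.character(classifyBias(0.45, 0.40, 0.49)), "biased_B")
})

test_that("all nine category cells map to the published groups", {
  de <- c("no_de", "A_higher", "B_higher", "A_higher", "B_higher",
          "no_de", "no_de", "A_higher", "B_higher")
  bias <- c("unbiased", "biased_A", "biased_B", "unbiased", "unbiased",
            "biased_A", "biased_B", "biased_B", "biased_A")
  cats <- assignCategory(de, bias)
  expect_equal(cats$category, 1:9)
  expect_equal(as.character(cats$group),
               c(rep("parental_legacy", 3), rep("absence_of_bias", 2),
                 rep("novel_bias", 4)))
  ## missing calls are skipped and counted
  cats2 <- assignCategory(c("no_de", NA), c("unbiased", "biased_A"))
  expect_equal(nrow(cats2), 1)
  expect_equal(S4Vectors::metadata(cats2)$n_skipped, 1)
})

test_that("cross-form comparison counts maternal-specific bias correctly", {
  c1 <- c(L1 = "biased_A", L2 = "biased_A", L3 = "unbiased",
          L4 = "biased_B", L5 = "biased_A")
  c2 <- c(L1 = "unbiased", L2 = "biased_A", L3 = "biased_B",
          L4 = "biased_B", L5 = "biased_B", L6 = "biased_A")
  ## form 1 maternal parent A, form 2 maternal parent B; L6 not shared
  cf <- compareForms(c1, c2, maternal1 = "A", maternal2 = "B")
  expect_equal(sum(cf$table), 5)
  ## identical-call loci sit on the diagonal
  expect_equal(cf$table["biased_A", "biased_A"], 1)
  ## L1: biased toward form1's maternal parent, unbiased in form2
  expect_true("L1" %in% cf$maternalSpecific$locus_id)
  ## L3: biased toward form2's maternal parent (B), unbiased in form1
  expect_true("L3" %in% cf$maternalSpecific$locus_id)
  ## L5 switches direction: in the switch cell, not the maternal list
  expect_false("L5" %in% cf$maternalSpecific$locus_id)
  expect_equal(cf$table["biased_A", "biased_B"], 1)
  ## identical call sets: off-diagonal empty
  cfSame <- compareForms(c1, c1, "A", "B")
  expect_equal(sum(cfSame$table) - sum(diag(cfSame$table)), 0)
})

test_that("balance test matches the closed form and chisq.test", {
  expect_equal(biasBalanceTest(100, 100)$statistic, 0)
  expect_equal(biasBalanceTest(100, 100)$p.value, 1)
  b1 <- biasBalanceTest(444, 545)
  expect_equal(b1$statistic, 2 * 50.5^2 / 494.5)
  expect_equal(b1$statistic, 10.31, tolerance = 1e-3)
  b2 <- biasBalanceTest(416, 515)
  expect_equal(b2$statistic, 10.53, tolerance = 1e-3)
  ## agreement with the stock goodness-of-fit test
  ref <- suppressWarnings(chisq.test(c(444, 545), p = c(0.5, 0.5)))
  expect_equal(b1$statistic, unname(ref$statistic))
  expect_equal(b1$p.value, ref$p.value)
  expect_equal(eldBalanceTest(0, 10)$statistic, 10)
  expect_error(biasBalanceTest(0, 0), "nA \\+ nB")
})
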