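# Statistical primitives and the two-sequence comparison protocol.

test_that("paired t-test matches the closed form and base-R oracle", {
  res <- pairedTTest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)

  expect_equal(pairedTTest(1:5, 1:5), list(t = 0, p = 1, df = 4L, n = 5L,
                                           mean_diff = 0, sd_diff = 0))
  expect_warning(res0 <- pairedTTest(1:5, 1:5 + 2), "identical")
  expect_equal(res0$p, 0)
  expect_error(pairedTTest(1, 1), "at least 2")
  expect_error(pairedTTest(1:3, 1:4), "paired")

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    res <- pairedTTest(x, y)
    d <- y - x
    tOracle <- mean(d) / (sd(d) / sqrt(12))
    expect_equal(res$t, tOracle, tolerance = 1e-10)
    expect_equal(res$p, 2 * pt(-abs(tOracle), 11), tolerance = 1e-10)
  }
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration for n <= 12", {
  # all-positive differences, n = 6: one-sided tail 1/64, two-sided 1/32
  res <- wilcoxonSignedRank(rep(0, 6), c(1.1, 2.3, 3.7, 4.2, 5.9, 6.4))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 32, tolerance = 1e-12)
  expect_error(wilcoxonSignedRank(1:4, 1:4), "zero")

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, 0.2, 1), 6)
    d <- d[d != 0]
    if (length(d) < 5 || anyDuplicated(abs(d))) next
    res <- wilcoxonSignedRank(numeric(length(d)), d)
    expect_equal(res$p, wilcoxonEnumOracle(d), tolerance = 1e-12,
                 label = sprintf("case %d (n=%d)", i, length(d)))
  }
  # ties or large n fall back to the continuity-corrected approximation
  res <- wilcoxonSignedRank(numeric(6), c(1, 1, 2, 3, -2, 4))
  expect_false(res$exact)
})

test_that("Shapiro-Wilk gate behaves under null and alternative", {
  expect_error(shapiroWilk(rep(1, 10)), "constant")
  set.seed(12)
  pNull <- replicate(200, shapiroWilk(rnorm(500))$p)
  ks <- suppressWarnings(ks.test(pNull, "punif"))
  expect_gt(ks$p.value, 0.01)
  pExp <- replicate(100, shapiroWilk(rexp(50))$p)
  expect_gte(mean(pExp < 0.01), 0.95)
})

test_that("Holm-Bonferroni matches the hand-computed step-down rule", {
  expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holmBonferroni(0.3), 0.3)
  capped <- holmBonferroni(c(0.5, 0.6, 0.9))
  expect_true(all(capped <= 1))
  expect_true(all(diff(sort(capped)) >= 0))
  expect_error(holmBonferroni(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    adj <- holmBonferroni(p)
    expect_equal(adj, holmOracle(p), tolerance = 1e-12)
    # dominated by plain Bonferroni, dominates raw p
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("Cohen's d conventions match their definitions", {
  expect_error(cohensDPaired(1:10, 1:10 + 2, mode = "diff_sd"), "zero denominator")
  set.seed(9)
  x <- rnorm(5000)
  y <- x + 0.5  # noise-free shift: pooled-SD d converges to 0.5
  expect_equal(cohensDPaired(x, y, "pooled_sd")$d, 0.5, tolerance = 0.02)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  expect_equal(cohensDPaired(x, y, "diff_sd")$d, mean(y - x) / sd(y - x),
               tolerance = 1e-12)
  expect_equal(cohensDPaired(x, y, "pooled_sd")$d,
               mean(y - x) / sqrt((var(x) + var(y)) / 2), tolerance = 1e-12)
})

test_that("paired t p-values are uniform under a Gaussian null", {
  set.seed(606)
  p <- replicate(4000, pairedTTest(rnorm(10), rnorm(10))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical sequences give corrected p = 1 and no effect sizes", {
  set.seed(14)
  k <- length(SUBREGIONS)
  m <- matrix(rnorm(k * 8, 300, 10), k, 8, dimnames = list(SUBREGIONS, NULL))
  mats <- list(T2_TSE = list(right = m, left = m * 0.98),
               T2_TSE_DRB = list(right = m, left = m * 0.98))
  cmp <- compareSequences(cohortFromMatrices(mats))
  tab <- referenceTable(cmp)
  expect_equal(nrow(tab), 44L)
  expect_equal(cmp@familySize, 44L)
  expect_true(all(tab$corrected_p == 1))
  expect_true(all(is.na(tab$cohens_d)))
  expect_true(all(is.na(cmp@varianceTest$p)))
})

test_that("sequence labels are symmetric up to sign of the difference", {
  spec <- cohortSpec(nHealthy = 10, seed = 51)
  cohort <- simulateCohort(spec)
  ab <- referenceTable(compareSequences(cohort))
  ba <- referenceTable(compareSequences(cohort, sequenceA = "T2_TSE_DRB",
                                        sequenceB = "T2_TSE"))
  key <- paste(ab$side, ab$region)
  i <- match(key, paste(ba$side, ba$region))
  expect_equal(ba$mean_diff_mm3[i], -ab$mean_diff_mm3, tolerance = 1e-12)
  expect_equal(ba$raw_p[i], ab$raw_p, tolerance = 1e-12)
  expect_equal(ba$corrected_p[i], ab$corrected_p, tolerance = 1e-12)
})

test_that("comparison protocol controls family-wise error under the null", {
  set.seed(321)
  reps <- 120
  null_effects <- data.frame(region = SUBREGIONS, shift_mm3 = 0,
                             noise_sd_mm3 = 3)
  hits <- vapply(seq_len(reps), function(r) {
    spec <- cohortSpec(nHealthy = 12, sequenceEffects = null_effects,
                       seed = 5000 + r)
    cmp <- compareSequences(simulateCohort(spec))
    any(referenceTable(cmp)$corrected_p < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("incomplete pairing across sequences is rejected", {
  spec <- cohortSpec(nHealthy = 6, seed = 77)
  tab <- cohortTable(simulateCohort(spec))
  tab <- tab[!(tab$subject_id == "sub0002" & tab$sequence == "T2_TSE_DRB"), ]
  expect_error(compareSequences(SubfieldExperiment(tab)), "pairing|subjects differ")
})
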