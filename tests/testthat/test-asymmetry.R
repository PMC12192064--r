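# The normative z-score and the |z| > 2 classification rule.

drbRef <- packagedReference("drb")

test_that("z-scores match the direct-formula oracle on random volumes", {
  set.seed(42)
  tab <- referenceTable(drbRef)
  for (i in 1:10) {
    r <- randomSideVolumes("p", "right", "T2_TSE_DRB")
    l <- randomSideVolumes("p", "left", "T2_TSE_DRB")
    res <- zscoreAsymmetry(r, l, drbRef)
    # independent recomputation: (right - left - mu) / sigma, region-wise
    rv <- volumes(aggregateVolumes(r))
    lv <- volumes(aggregateVolumes(l))
    j <- match(res$region, tab$region)
    oracle <- (rv[res$region] - lv[res$region] - tab$mean_mm3[j]) / tab$sd_mm3[j]
    expect_equal(res$z, unname(oracle), tolerance = 1e-12)
  }
})

test_that("a patient at the healthy mean difference scores z = 0 everywhere", {
  tab <- referenceTable(drbRef)
  mu <- stats::setNames(tab$mean_mm3, tab$region)[SUBREGIONS]
  base <- stats::setNames(rep(500, 19), SUBREGIONS)
  r <- SideVolumes(base + mu / 2, "p", "right", "drb")
  l <- SideVolumes(base - mu / 2, "p", "left", "drb")
  res <- zscoreAsymmetry(r, l, drbRef)
  expect_equal(res$z[res$label_class == "subregion"], rep(0, 19),
               tolerance = 1e-12)
  rep <- classifyAsymmetry(res)
  expect_equal(rep@nSubregionsFlagged, 0L)
  expect_equal(rep@lateralization, "indeterminate")
})

test_that("side swap with a symmetric reference exactly negates z", {
  set.seed(17)
  symRef <- drbRef
  symRef@table$mean_mm3 <- 0
  r <- randomSideVolumes("p", "right", "T2_TSE_DRB")
  l <- randomSideVolumes("p", "left", "T2_TSE_DRB")
  res <- zscoreAsymmetry(r, l, symRef)
  rSwap <- SideVolumes(volumes(l), "p", "right", "drb")
  lSwap <- SideVolumes(volumes(r), "p", "left", "drb")
  resSwap <- zscoreAsymmetry(rSwap, lSwap, symRef)
  expect_equal(resSwap$z, -res$z, tolerance = 1e-12)
})

test_that("z is monotone in each side's volume", {
  set.seed(23)
  r <- randomSideVolumes("p", "right", "T2_TSE_DRB")
  l <- randomSideVolumes("p", "left", "T2_TSE_DRB")
  z0 <- zscoreAsymmetry(r, l, drbRef)
  vr <- volumes(r); vr["CA1-Head"] <- vr["CA1-Head"] + 10
  z1 <- zscoreAsymmetry(SideVolumes(vr, "p", "right", "drb"), l, drbRef)
  expect_gt(z1$z[z1$region == "CA1-Head"], z0$z[z0$region == "CA1-Head"])
  vl <- volumes(l); vl["CA1-Head"] <- vl["CA1-Head"] + 10
  z2 <- zscoreAsymmetry(r, SideVolumes(vl, "p", "left", "drb"), drbRef)
  expect_lt(z2$z[z2$region == "CA1-Head"], z0$z[z0$region == "CA1-Head"])
})

test_that("boundary z = +/-2 is not flagged (strict inequality)", {
  # reference with exactly representable mu = 0, sigma = 10 so that a
  # subregion difference of 20 gives z = 2 with no rounding
  ref <- drbRef
  ref@table$mean_mm3 <- 0
  ref@table$sd_mm3 <- 10
  base <- stats::setNames(rep(800, 19), SUBREGIONS)
  r <- SideVolumes(base + 10, "p", "right", "drb")
  l <- SideVolumes(base - 10, "p", "left", "drb")
  res <- zscoreAsymmetry(r, l, ref)
  subs <- res$label_class == "subregion"
  expect_identical(res$z[subs], rep(2, 19))
  rep <- classifyAsymmetry(res)
  expect_false(any(rep@results$flagged[subs]))
  expect_equal(rep@nSubregionsFlagged, 0L)
  # combined labels sum member diffs and are legitimately far outside
  expect_equal(rep@nCombinedFlagged, 3L)
})

test_that("sequence mismatch between patient and reference is a hard error", {
  r <- randomSideVolumes("p", "right", "T2_TSE")
  l <- randomSideVolumes("p", "left", "T2_TSE")
  expect_error(zscoreAsymmetry(r, l, drbRef), "does not match reference")
  expect_s3_class(zscoreAsymmetry(r, l, drbRef, allowSequenceMismatch = TRUE),
                  "data.frame")
})

test_that("classification counts and lateralization recount from flags", {
  pat <- hsExampleVolumes()
  res <- zscoreAsymmetry(pat$right, pat$left, drbRef)
  rep <- classifyAsymmetry(res)
  expect_equal(rep@nSubregionsFlagged, sum(res$flagged & res$label_class == "subregion"))
  expect_equal(rep@nCombinedFlagged, 3L)
  expect_equal(rep@lateralization, "right_smaller")
  # duplicate region rows rejected
  expect_error(classifyAsymmetry(rbind(res, res[1, ])), "duplicate region")
  # mixed flag signs give indeterminate
  res2 <- res
  res2$diff_mm3[res2$region == "CA1-Head"] <- 200
  expect_equal(classifyAsymmetry(res2)@lateralization, "indeterminate")
})

test_that("cohort z-matrix agrees with per-patient scoring", {
  spec <- cohortSpec(nHealthy = 6, sequences = "T2_TSE_DRB",
                     asymmetryParams = {
                       tab <- referenceTable(drbRef)
                       tab[match(SUBREGIONS, tab$region), ]
                     }, seed = 64)
  cohort <- simulateCohort(spec)
  Z <- asymmetryZMatrix(cohort, drbRef)
  expect_equal(dim(Z), c(22L, 6L))
  tab <- cohortTable(cohort)
  s <- "sub0003"
  one <- tab[tab$subject_id == s, ]
  toSV <- function(side) {
    rows <- one[one$side == side, ]
    SideVolumes(stats::setNames(rows$volume_mm3, rows$region), s, side,
                "T2_TSE_DRB")
  }
  res <- zscoreAsymmetry(toSV("right"), toSV("left"), drbRef)
  expect_equal(Z[res$region, s], stats::setNames(res$z, res$region),
               tolerance = 1e-12)
})

test_that("null patients are flagged at about the nominal 4.55% rate", {
  # patients drawn from the reference distribution itself
  set.seed(2024)
  tab <- referenceTable(drbRef)
  ap <- tab[match(SUBREGIONS, tab$region), ]
  spec <- cohortSpec(nHealthy = 20000, asymmetryParams = ap,
                     sequences = "T2_TSE_DRB", seed = 77)
  Z <- asymmetryZMatrix(simulateCohort(spec), drbRef)
  rate <- rowMeans(abs(Z[SUBREGIONS, ]) > 2)
  expect_true(all(rate > 0.040 & rate < 0.052))
})
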