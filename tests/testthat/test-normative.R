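# Normative reference construction, packaged values, symmetry screen.

test_that("two-subject reference matches the closed form", {
  set.seed(21)
  k <- length(SUBREGIONS)
  B <- matrix(300, k, 2, dimnames = list(SUBREGIONS, NULL))
  d <- matrix(rnorm(2 * k, 0, 15), k, 2)
  mats <- list(T2_TSE = list(right = B + d / 2, left = B - d / 2))
  ref <- buildReference(cohortFromMatrices(mats), "T2_TSE")
  tab <- referenceTable(ref)
  i <- match(SUBREGIONS, tab$region)
  expect_equal(tab$mean_mm3[i], unname((d[, 1] + d[, 2]) / 2), tolerance = 1e-12)
  expect_equal(tab$sd_mm3[i], unname(abs(d[, 1] - d[, 2]) / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(ref@nControls, 2L)
})

test_that("an exactly symmetric cohort is rejected for zero variance", {
  k <- length(SUBREGIONS)
  B <- matrix(rep(seq(100, 300, length.out = k), 4), k, 4,
              dimnames = list(SUBREGIONS, NULL))
  mats <- list(T2_TSE = list(right = B, left = B))
  cohort <- cohortFromMatrices(mats)
  expect_error(buildReference(cohort, "T2_TSE"), "zero-variance")
})

test_that("packaged reference transcription is frozen", {
  drb <- referenceTable(packagedReference("drb"))
  tse <- referenceTable(packagedReference("tse"))
  expect_equal(nrow(drb), 22L)
  expect_true(all(drb$sd_mm3 > 0) && all(tse$sd_mm3 > 0))
  expect_equal(drb$mean_mm3[drb$region == "Parasubiculum"], -7.6)
  expect_equal(drb$sd_mm3[drb$region == "Parasubiculum"], 13.8)
  expect_equal(tse$mean_mm3[tse$region == "Whole_hippocampus"], 0.6)
  expect_equal(tse$sd_mm3[tse$region == "Whole_hippocampus"], 181.9)
  expect_equal(packagedReference("T2_TSE_DRB")@nControls, 20L)
  # bit-stability of the shipped table
  path <- system.file("extdata", "normative_reference.tsv", package = "hippasym")
  expect_equal(unname(tools::md5sum(path)), "04a704daf349e8cd5f1ee922ef377f7b")
})

test_that("reference recovery from a simulated normative cohort", {
  # cohort whose right-left differences follow the packaged DRB model
  n <- 2000
  drb <- referenceTable(packagedReference("drb"))
  ap <- drb[match(SUBREGIONS, drb$region), ]
  spec <- cohortSpec(nHealthy = n, asymmetryParams = ap,
                     sequences = "T2_TSE_DRB", seed = 909)
  ref <- buildReference(simulateCohort(spec), "T2_TSE_DRB")
  tab <- referenceTable(ref)
  i <- match(SUBREGIONS, tab$region)
  expect_true(all(abs(tab$mean_mm3[i] - ap$mean_mm3) < 4 * ap$sd_mm3 / sqrt(n)))
  expect_true(all(abs(tab$sd_mm3[i] / ap$sd_mm3 - 1) < 0.10))
})

test_that("reference is translation-equivariant and side-swap antisymmetric", {
  set.seed(77)
  cohort <- gaussianHealthyCohort(12, mu = 3, sigma = 8)
  ref <- referenceTable(buildReference(cohort, "T2_TSE"))

  # add c to every right-side volume: subregion means shift by c,
  # combined-label means by c * |members|
  cc <- 5
  tab <- cohortTable(cohort)
  tab$volume_mm3[tab$side == "right"] <- tab$volume_mm3[tab$side == "right"] + cc
  refShift <- referenceTable(buildReference(SubfieldExperiment(tab), "T2_TSE"))
  shift <- refShift$mean_mm3 - ref$mean_mm3[match(refShift$region, ref$region)]
  members <- stats::setNames(rep(1, 22), ref$region)
  for (lab in names(combinedLabels(hier))) {
    members[lab] <- length(combinedLabels(hier)[[lab]])
  }
  expect_equal(shift, unname(cc * members[refShift$region]), tolerance = 1e-9)
  expect_equal(refShift$sd_mm3, ref$sd_mm3[match(refShift$region, ref$region)],
               tolerance = 1e-9)

  # swapping hemisphere labels negates means, preserves SDs
  tab2 <- cohortTable(cohort)
  tab2$side <- ifelse(tab2$side == "right", "left", "right")
  refSwap <- referenceTable(buildReference(SubfieldExperiment(tab2), "T2_TSE"))
  i <- match(ref$region, refSwap$region)
  expect_equal(refSwap$mean_mm3[i], -ref$mean_mm3, tolerance = 1e-12)
  expect_equal(refSwap$sd_mm3[i], ref$sd_mm3, tolerance = 1e-12)
})

test_that("symmetry screen: identical sides give t = 0 and corrected p = 1", {
  set.seed(31)
  cohort <- gaussianHealthyCohort(10, mu = 0, sigma = 6)
  tab <- cohortTable(cohort)
  # make one region exactly symmetric
  ca1 <- tab$region == "CA1-Head"
  right <- tab[ca1 & tab$side == "right", ]
  tab$volume_mm3[ca1 & tab$side == "left"] <-
    right$volume_mm3[match(tab$subject_id[ca1 & tab$side == "left"],
                           right$subject_id)]
  scr <- referenceTable(symmetryScreen(SubfieldExperiment(tab), "T2_TSE"))
  row <- scr[scr$region == "CA1-Head", ]
  expect_equal(row$t, 0)
  expect_equal(row$corrected_p, 1)
  expect_true(all(scr$corrected_p >= scr$raw_p - 1e-12))
  expect_true(all(scr$corrected_p <= 1))
})

test_that("symmetry screen controls the family-wise error rate", {
  set.seed(555)
  reps <- 300
  hits <- vapply(seq_len(reps), function(r) {
    cohort <- gaussianHealthyCohort(10, mu = 0, sigma = 6)
    scr <- referenceTable(symmetryScreen(cohort, "T2_TSE"))
    any(scr$corrected_p < 0.05)
  }, logical(1))
  # binomial upper bound at the nominal 5% level
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("symmetry screen detects a one-region 1-SD shift", {
  set.seed(808)
  reps <- 60
  wins <- vapply(seq_len(reps), function(r) {
    k <- length(SUBREGIONS)
    n <- 20
    B <- matrix(rnorm(k * n, 300, 5), k, n, dimnames = list(SUBREGIONS, NULL))
    a <- matrix(rnorm(k * n, 0, 10), k, n, dimnames = list(SUBREGIONS, NULL))
    a["CA1-Head", ] <- a["CA1-Head", ] + 10  # 1 SD shift
    mats <- list(T2_TSE = list(right = B + a / 2, left = B - a / 2))
    scr <- referenceTable(symmetryScreen(cohortFromMatrices(mats), "T2_TSE"))
    scr$region[which.min(scr$corrected_p)] == "CA1-Head"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("cohens d is attached only to rows significant after correction", {
  set.seed(99)
  k <- length(SUBREGIONS)
  n <- 20
  B <- matrix(rnorm(k * n, 300, 5), k, n, dimnames = list(SUBREGIONS, NULL))
  a <- matrix(rnorm(k * n, 0, 4), k, n, dimnames = list(SUBREGIONS, NULL))
  a["Subiculum-body", ] <- a["Subiculum-body", ] - 8  # strong asymmetry
  mats <- list(T2_TSE = list(right = B + a / 2, left = B - a / 2))
  scr <- referenceTable(symmetryScreen(cohortFromMatrices(mats), "T2_TSE"))
  expect_identical(is.na(scr$cohens_d), scr$corrected_p >= 0.05)
  sig <- scr[scr$region == "Subiculum-body", ]
  expect_lt(sig$corrected_p, 0.05)
  expect_equal(sig$cohens_d, sig$mean_diff_mm3 / sig$sd_diff_mm3)
})
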