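# Shared fixtures and independent oracles for the test suite.

hier <- canonicalHierarchy()
SUBREGIONS <- subregions(hier)
SCORED <- scoredRegions(hier)

# random complete SideVolumes for one hemisphere
randomSideVolumes <- function(subject = "s1", side = "right",
                              sequence = "T2_TSE", scale = 200) {
  SideVolumes(stats::setNames(runif(length(SUBREGIONS), 10, scale), SUBREGIONS),
              subjectID = subject, side = side, sequence = sequence)
}

# long-format cohort records from per-side volume matrices
# mats: named list sequence -> list(right = 19 x n, left = 19 x n)
cohortFromMatrices <- function(mats, group = "healthy") {
  recs <- do.call(rbind, lapply(names(mats), function(sq) {
    do.call(rbind, lapply(c("right", "left"), function(sd) {
      m <- mats[[sq]][[sd]]
      n <- ncol(m)
      data.frame(
        subject_id = rep(sprintf("s%03d", seq_len(n)), each = nrow(m)),
        group = rep(group, length.out = n * nrow(m)),
        sequence = sq, side = sd,
        region = rep(rownames(m), times = n),
        volume_mm3 = as.vector(m),
        stringsAsFactors = FALSE
      )
    }))
  }))
  SubfieldExperiment(recs)
}

# healthy cohort with iid N(mu, sigma) right-left differences per region
gaussianHealthyCohort <- function(n, mu = 0, sigma = 10, base = 300,
                                  sequence = "T2_TSE") {
  k <- length(SUBREGIONS)
  B <- matrix(rnorm(k * n, base, 5), k, n, dimnames = list(SUBREGIONS, NULL))
  a <- matrix(rnorm(k * n, mu, sigma), k, n)
  mats <- list(list(right = B + a / 2, left = B - a / 2))
  names(mats) <- sequence
  rownames(mats[[1]]$left) <- SUBREGIONS
  cohortFromMatrices(mats)
}

# exhaustive-enumeration oracle for the two-sided Wilcoxon signed-rank
# test (tie-free, zero-free differences): enumerates all 2^n sign
# assignments of the ranked |d| and doubles the smaller tail.
wilcoxonEnumOracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% r)
  pLower <- mean(wAll <= wObs)
  pUpper <- mean(wAll >= wObs)
  min(1, 2 * min(pLower, pUpper))
}

# independent step-down Holm oracle (direct implementation of the rule)
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
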