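# Synthetic cohort generator: healthy bilateral subfield volumes with a
# Gaussian right-minus-left asymmetry model, an optional second sequence
# with systematic shifts plus extra segmentation noise, and unilateral
# pathology profiles.

.PATHOLOGIES <- c("HS_right", "HS_left", "edema_right", "edema_left", "none")

#' Pathology profile of the packaged hippocampal sclerosis example
#'
#' Per-subfield multiplicative volume factors of the affected side, taken
#' as the right/left volume ratios of the packaged right-sided HS patient
#' (e.g. CA4-body 40.6/103.4 = 0.393, CA1-Head 251.1/437.4 = 0.574).
#' Applied at severity s the factor becomes \code{1 + s * (factor - 1)},
#' so severity 0 is the identity and severity 1 reproduces the example's
#' atrophy pattern.
#'
#' @return named numeric vector of 19 factors in (0, 1].
#' @examples
#' round(hsPathologyProfile()[["CA4-body"]], 3)
#' @export
hsPathologyProfile <- function() {
  pat <- hsExampleVolumes()
  r <- pat$right@volumes
  l <- pat$left@volumes
  sub <- subregions(canonicalHierarchy())
  stats::setNames(r[sub] / l[sub], sub)
}

.uniformProfile <- function(factor, hierarchy = canonicalHierarchy()) {
  sub <- subregions(hierarchy)
  stats::setNames(rep(factor, length(sub)), sub)
}

#' Specify a synthetic subfield cohort
#'
#' Builds a validated [CohortSpec-class].  The defaults emulate the study
#' conditions of the packaged reference tables: asymmetry parameters are
#' the packaged conventional-sequence (T2 TSE) normative rows; base
#' bilateral means are the mean of the right and left per-region mean
#' volumes under that sequence; sequence effects (shift and extra noise of
#' the second, deep-learning-reconstructed sequence) are the
#' right-hippocampus mean-difference and SD columns of the packaged
#' sequence comparison summary; between-subject coefficient of variation
#' defaults to 0.10, a free calibration knob since cross-subject volume
#' SDs are not part of the packaged summaries.
#'
#' @param nHealthy number of healthy controls (default 20).
#' @param patients data.frame with columns \code{pathology} (one of
#'   \code{HS_right}, \code{HS_left}, \code{edema_right},
#'   \code{edema_left}, \code{none}) and \code{severity} in [0, 1].
#' @param baseMeans named numeric of 19 bilateral mean volumes (mm^3).
#' @param betweenSubjectCV fraction of each base mean used as the SD of
#'   the latent bilateral mean across subjects.
#' @param asymmetryParams data.frame \code{region}, \code{mean_mm3},
#'   \code{sd_mm3} for the 19 subfields.
#' @param sequenceEffects data.frame \code{region}, \code{shift_mm3},
#'   \code{noise_sd_mm3} for the 19 subfields.
#' @param sequences one or two sequence tags (first = base sequence).
#' @param seed RNG seed.
#' @return a [CohortSpec-class].
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(nHealthy = 20,
                       patients = data.frame(pathology = character(),
                                             severity = numeric()),
                       baseMeans = NULL,
                       betweenSubjectCV = 0.10,
                       asymmetryParams = NULL,
                       sequenceEffects = NULL,
                       sequences = c("T2_TSE", "T2_TSE_DRB"),
                       seed = 1L) {
  hier <- canonicalHierarchy()
  sub <- subregions(hier)
  if (is.null(baseMeans) || is.null(sequenceEffects)) {
    ss <- sequenceVolumeSummary()
    ss <- ss[ss$region %in% sub, , drop = FALSE]
    if (is.null(baseMeans)) {
      bySide <- split(ss$mean_tse_mm3, ss$region)
      baseMeans <- vapply(bySide, mean, numeric(1))[sub]
    }
    if (is.null(sequenceEffects)) {
      r <- ss[ss$side == "right", , drop = FALSE]
      sequenceEffects <- data.frame(region = r$region,
                                    shift_mm3 = r$mean_diff_mm3,
                                    noise_sd_mm3 = r$sd_diff_mm3,
                                    stringsAsFactors = FALSE)
    }
  }
  if (is.null(asymmetryParams)) {
    ref <- referenceTable(packagedReference("T2_TSE"))
    asymmetryParams <- ref[ref$region %in% sub, , drop = FALSE]
  }
  sequences <- vapply(sequences, matchSequence, character(1), USE.NAMES = FALSE)
  new("CohortSpec",
      nHealthy = as.integer(nHealthy),
      patients = patients,
      baseMeans = baseMeans,
      betweenSubjectCV = betweenSubjectCV,
      asymmetryParams = asymmetryParams,
      sequenceEffects = sequenceEffects,
      sequences = sequences,
      seed = as.integer(seed))
}

#' Simulate a subfield cohort
#'
#' Draws a cohort from the generative model described in
#' [CohortSpec-class].  Per healthy subject and subfield, a latent
#' bilateral mean \eqn{B \sim N(\mu_{base}, cv\,\mu_{base})} and an
#' asymmetry \eqn{a \sim N(\mu_r, \sigma_r)} give right = B + a/2,
#' left = B - a/2, so the right-minus-left difference has exactly the
#' normative distribution.  If a second sequence is requested, its
#' per-hemisphere volumes are the first sequence's plus a systematic
#' per-subfield shift and independent zero-mean Gaussian noise.  Patients
#' additionally have affected-side subfield volumes multiplied by
#' severity-interpolated pathology-profile factors (HS: the packaged
#' sclerosis profile; edema: a uniform 1.2 enlargement).  Combined labels
#' are always derived by aggregation downstream, never sampled.  Negative
#' draws are truncated at 0 with a warning; at the default parameters
#' truncation is essentially impossible.
#'
#' The seed in the spec makes the output byte-identical across calls.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SubfieldExperiment-class] with \code{nHealthy +
#'   nrow(patients)} subjects, both hemispheres, and the requested
#'   sequences.
#' @examples
#' cohort <- simulateCohort(cohortSpec(nHealthy = 5, seed = 42))
#' cohort
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  hier <- canonicalHierarchy()
  sub <- subregions(hier)
  k <- length(sub)
  nPat <- nrow(spec@patients)
  n <- spec@nHealthy + nPat
  if (n < 1L) stop("empty cohort", call. = FALSE)
  ids <- sprintf("sub%04d", seq_len(n))
  groups <- c(rep("healthy", spec@nHealthy),
              vapply(as.character(spec@patients$pathology), function(p) {
                switch(p, HS_right = , HS_left = "HS",
                       edema_right = , edema_left = "edema",
                       "epilepsy_no_lesion")
              }, character(1)))

  base <- spec@baseMeans[sub]
  ap <- spec@asymmetryParams[match(sub, spec@asymmetryParams$region), ]
  B <- matrix(stats::rnorm(k * n, mean = base, sd = spec@betweenSubjectCV * base),
              nrow = k, ncol = n)
  a <- matrix(stats::rnorm(k * n, mean = ap$mean_mm3, sd = ap$sd_mm3),
              nrow = k, ncol = n)
  right <- B + a / 2
  left <- B - a / 2

  if (nPat) {
    hs <- hsPathologyProfile()[sub]
    edema <- .uniformProfile(1.2, hier)[sub]
    for (j in seq_len(nPat)) {
      p <- as.character(spec@patients$pathology[j])
      if (p == "none") next
      sev <- spec@patients$severity[j]
      profile <- if (startsWith(p, "HS")) hs else edema
      fac <- 1 + sev * (profile - 1)
      col <- spec@nHealthy + j
      if (endsWith(p, "right")) {
        right[, col] <- right[, col] * fac
      } else {
        left[, col] <- left[, col] * fac
      }
    }
  }

  mats <- list(list(sequence = spec@sequences[1L], right = right, left = left))
  if (length(spec@sequences) == 2L) {
    se <- spec@sequenceEffects[match(sub, spec@sequenceEffects$region), ]
    noise <- function() matrix(stats::rnorm(k * n, mean = 0, sd = se$noise_sd_mm3),
                               nrow = k, ncol = n)
    mats[[2L]] <- list(sequence = spec@sequences[2L],
                       right = right + se$shift_mm3 + noise(),
                       left = left + se$shift_mm3 + noise())
  }

  nNeg <- sum(vapply(mats, function(m) {
    as.numeric(sum(m$right < 0) + sum(m$left < 0))
  }, numeric(1)))
  if (nNeg > 0) {
    warning(sprintf("%d of %d simulated volumes were negative and truncated at 0",
                    nNeg, 2L * k * n * length(mats)), call. = FALSE)
    mats <- lapply(mats, function(m) {
      m$right <- pmax(m$right, 0)
      m$left <- pmax(m$left, 0)
      m
    })
  }

  assayMat <- do.call(cbind, unlist(lapply(mats, function(m) list(m$right, m$left)),
                                    recursive = FALSE))
  nScanPerSide <- n
  scanSeq <- rep(vapply(mats, `[[`, character(1), "sequence"), each = 2L * nScanPerSide)
  scanSide <- rep(rep(c("right", "left"), each = nScanPerSide), times = length(mats))
  scanSubj <- rep(ids, times = 2L * length(mats))
  dimnames(assayMat) <- list(sub, paste(scanSubj, scanSeq, scanSide, sep = "|"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volume_mm3 = assayMat),
    colData = S4Vectors::DataFrame(
      subject_id = scanSubj,
      group = rep(groups, times = 2L * length(mats)),
      sequence = scanSeq,
      side = scanSide,
      row.names = colnames(assayMat)
    ),
    metadata = list(provenance = sprintf("simulateCohort(seed = %d)", spec@seed))
  )
  new("SubfieldExperiment", se)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d healthy + %d patients, seed %d\n",
              object@nHealthy, nrow(object@patients), object@seed))
  cat(sprintf("  sequences: %s; between-subject CV %.2f\n",
              paste(object@sequences, collapse = " -> "),
              object@betweenSubjectCV))
})
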