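#' @import methods
NULL

.SIDES <- c("right", "left")
.SEQUENCES <- c("T2_TSE", "T2_TSE_DRB")
.GROUPS <- c("healthy", "HS", "FCD", "edema", "epilepsy_no_lesion")

#' Hippocampal region hierarchy
#'
#' Catalogue of the 19 hippocampal subfields produced by automated subfield
#' segmentation together with the anatomical aggregation used throughout the
#' package: four merged labels (HEAD, BODY, TAIL, FISSURE) that partition the
#' subfields, and three combined labels (whole hippocampal head, whole
#' hippocampal body, whole hippocampus) obtained by summing member subfield
#' volumes.  The whole-hippocampus label has 18 members: the hippocampal
#' fissure, being a CSF space rather than tissue, is excluded.
#'
#' An alias table maps alternative spellings (FreeSurfer v7 output names,
#' CA3 vs CA2/3, case variants) onto the canonical names.
#'
#' @slot subregions character vector of the 19 canonical subfield names, in
#'   catalogue order.  Sums over members are always taken in this order so
#'   that derived volumes are bit-reproducible.
#' @slot mergedLabels named list (HEAD, BODY, TAIL, FISSURE) of member
#'   subregions; a partition of \code{subregions}.
#' @slot combinedLabels named list of the three combined labels and their
#'   member subregions.
#' @slot aliases named character vector mapping alternative spellings to
#'   canonical names.
#'
#' @seealso [canonicalHierarchy()], [resolveRegions()], [aggregateVolumes()]
#' @export
setClass("RegionHierarchy",
  representation(
    subregions = "character",
    mergedLabels = "list",
    combinedLabels = "list",
    aliases = "character"
  )
)

setValidity("RegionHierarchy", function(object) {
  msg <- character()
  sr <- object@subregions
  if (anyDuplicated(sr)) {
    msg <- c(msg, "subregion names must be unique")
  }
  ml <- object@mergedLabels
  if (!setequal(names(ml), c("HEAD", "BODY", "TAIL", "FISSURE"))) {
    msg <- c(msg, "merged labels must be HEAD, BODY, TAIL, FISSURE")
  }
  members <- unlist(ml, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, sr)) {
    msg <- c(msg, "merged labels must partition the subregions (disjoint, exhaustive)")
  }
  cl <- object@combinedLabels
  wh <- cl[["Whole_hippocampus"]]
  if (!is.null(wh)) {
    fissure <- ml[["FISSURE"]]
    if (length(wh) != length(sr) - length(fissure) || any(fissure %in% wh)) {
      msg <- c(msg, "Whole_hippocampus must contain all subregions except the fissure")
    }
  } else {
    msg <- c(msg, "combined labels must include Whole_hippocampus")
  }
  if (!all(unlist(cl, use.names = FALSE) %in% sr)) {
    msg <- c(msg, "combined-label members must be subregions")
  }
  al <- object@aliases
  if (length(al) && (is.null(names(al)) || anyDuplicated(names(al)) ||
                     !all(al %in% c(sr, names(ml), names(cl))))) {
    msg <- c(msg, "every alias must map to exactly one canonical label")
  }
  if (length(msg)) msg else TRUE
})

#' Per-hemisphere subfield volumes of one scan
#'
#' Holds the subfield volumes (mm^3) measured on one hemisphere of one
#' subject under one acquisition sequence.  Region names are canonicalized
#' against the [RegionHierarchy-class] at construction.
#'
#' @slot subjectID opaque subject identifier.
#' @slot side \code{"right"} or \code{"left"}.
#' @slot sequence sequence tag, \code{"T2_TSE"} or \code{"T2_TSE_DRB"}.
#' @slot volumes named numeric vector of finite, non-negative volumes (mm^3).
#'
#' @seealso [SideVolumes()], [readSubfieldVolumes()], [aggregateVolumes()]
#' @export
setClass("SideVolumes",
  representation(
    subjectID = "character",
    side = "character",
    sequence = "character",
    volumes = "numeric"
  )
)

setValidity("SideVolumes", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L || !nzchar(object@subjectID)) {
    msg <- c(msg, "subjectID must be a single non-empty string")
  }
  if (length(object@side) != 1L || !object@side %in% .SIDES) {
    msg <- c(msg, "side must be 'right' or 'left'")
  }
  if (length(object@sequence) != 1L || !object@sequence %in% .SEQUENCES) {
    msg <- c(msg, sprintf("sequence must be one of: %s", paste(.SEQUENCES, collapse = ", ")))
  }
  v <- object@volumes
  if (is.null(names(v)) || anyDuplicated(names(v))) {
    msg <- c(msg, "volumes must be uniquely named by region")
  }
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    msg <- c(msg, "volumes must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Normative reference for right-minus-left volume differences
#'
#' Per-region mean and standard deviation of the intra-individual
#' right-minus-left subfield volume difference in healthy controls, for one
#' acquisition sequence.  These are the \eqn{\mu_{healthy}} and
#' \eqn{\sigma_{healthy}} of the asymmetry z-score
#' \deqn{z = \frac{(V_{right} - V_{left}) - \mu_{healthy}}{\sigma_{healthy}}.}
#' Rows cover exactly the 22 scored regions (19 subfields plus the three
#' combined labels).
#'
#' @slot sequence sequence tag the reference applies to.
#' @slot nControls number of healthy controls behind the estimates.
#' @slot table data.frame with columns \code{region}, \code{mean_mm3},
#'   \code{sd_mm3}; all SDs strictly positive.
#' @slot source \code{"packaged"} for the shipped reference values or
#'   \code{"built"} for [buildReference()] output.
#'
#' @seealso [packagedReference()], [buildReference()], [referenceZ()]
#' @export
setClass("NormativeReference",
  representation(
    sequence = "character",
    nControls = "integer",
    table = "data.frame",
    source = "character"
  )
)

setValidity("NormativeReference", function(object) {
  msg <- character()
  if (!object@sequence %in% .SEQUENCES) {
    msg <- c(msg, "unknown sequence tag")
  }
  tab <- object@table
  need <- c("region", "mean_mm3", "sd_mm3")
  if (!all(need %in% names(tab))) {
    msg <- c(msg, sprintf("table must have columns %s", paste(need, collapse = ", ")))
  } else {
    scored <- scoredRegions(canonicalHierarchy())
    if (!setequal(tab$region, scored) || anyDuplicated(tab$region)) {
      msg <- c(msg, "reference rows must cover exactly the 22 scored regions")
    }
    if (any(!is.finite(tab$mean_mm3)) || any(!is.finite(tab$sd_mm3))) {
      msg <- c(msg, "reference means and SDs must be finite")
    } else if (any(tab$sd_mm3 <= 0)) {
      msg <- c(msg, sprintf("sd_mm3 must be > 0 for every region (violated: %s)",
                            paste(tab$region[tab$sd_mm3 <= 0], collapse = ", ")))
    }
  }
  if (!object@source %in% c("packaged", "built")) {
    msg <- c(msg, "source must be 'packaged' or 'built'")
  }
  if (length(msg)) msg else TRUE
})

#' Left/right symmetry screen of a healthy cohort
#'
#' Result of the paired-test screen that checks the symmetry assumption
#' underlying the normative model: per scored region, a two-tailed paired
#' t-test of right vs left volumes in healthy controls,
#' Holm–Bonferroni-corrected across the 22 regions (capped at 1), with
#' Cohen's d (mean difference / SD of differences) attached to rows that
#' remain significant after correction.
#'
#' @slot sequence sequence tag screened.
#' @slot alpha significance level used for the d-attachment rule.
#' @slot nSubjects number of paired subjects.
#' @slot table data.frame with columns \code{region}, \code{mean_diff_mm3},
#'   \code{sd_diff_mm3}, \code{t}, \code{raw_p}, \code{corrected_p},
#'   \code{cohens_d} (NA where not significant).
#'
#' @seealso [symmetryScreen()]
#' @export
setClass("SymmetryScreen",
  representation(
    sequence = "character",
    alpha = "numeric",
    nSubjects = "integer",
    table = "data.frame"
  )
)

setValidity("SymmetryScreen", function(object) {
  tab <- object@table
  msg <- character()
  if (any(tab$corrected_p + 1e-12 < tab$raw_p)) {
    msg <- c(msg, "corrected p-values must be >= raw p-values")
  }
  if (any(tab$corrected_p > 1)) {
    msg <- c(msg, "corrected p-values must be capped at 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-patient asymmetry report
#'
#' Classification of one patient's 22 asymmetry z-scores under the
#' pathology rule |z| > 2 (strict; the boundary z = +/-2 is not flagged),
#' with separate counts for the 19 subfields and the 3 combined labels and a
#' descriptive lateralization call derived from the signs of the flagged
#' right-minus-left differences.
#'
#' @slot subjectID subject identifier.
#' @slot sequence sequence tag of the scored scan.
#' @slot threshold z magnitude above which a region is flagged (default 2).
#' @slot results data.frame of 22 rows with columns \code{region},
#'   \code{label_class}, \code{right_mm3}, \code{left_mm3}, \code{diff_mm3},
#'   \code{z}, \code{flagged}.
#' @slot nSubregionsFlagged flagged subfields (out of 19).
#' @slot nCombinedFlagged flagged combined labels (out of 3).
#' @slot lateralization \code{"right_smaller"}, \code{"left_smaller"} or
#'   \code{"indeterminate"}.
#'
#' @seealso [zscoreAsymmetry()], [classifyAsymmetry()], [writeReport()]
#' @export
setClass("AsymmetryReport",
  representation(
    subjectID = "character",
    sequence = "character",
    threshold = "numeric",
    results = "data.frame",
    nSubregionsFlagged = "integer",
    nCombinedFlagged = "integer",
    lateralization = "character"
  )
)

setValidity("AsymmetryReport", function(object) {
  msg <- character()
  res <- object@results
  if (anyDuplicated(res$region)) {
    msg <- c(msg, "duplicate region rows in results")
  }
  flg <- res$flagged
  if (object@nSubregionsFlagged != sum(flg & res$label_class == "subregion")) {
    msg <- c(msg, "nSubregionsFlagged does not match a recount of flagged subregion rows")
  }
  if (object@nCombinedFlagged != sum(flg & res$label_class == "combined")) {
    msg <- c(msg, "nCombinedFlagged does not match a recount of flagged combined rows")
  }
  if (!object@lateralization %in% c("right_smaller", "left_smaller", "indeterminate")) {
    msg <- c(msg, "invalid lateralization value")
  }
  if (any(res$flagged != (abs(res$z) > object@threshold))) {
    msg <- c(msg, "flags must equal strict |z| > threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Sequence-comparison table
#'
#' Output of [compareSequences()]: per scored region and hemisphere, the
#' paired two-tailed t-test comparing volumes between two acquisition
#' sequences, Holm–Bonferroni-corrected over all tests run in the
#' invocation, with Cohen's d attached to rows significant after correction,
#' plus a paired Wilcoxon signed-rank screen on per-region cross-subject
#' variances as a nonparametric check of variance comparability.
#'
#' @slot sequenceA,sequenceB the two sequence tags compared (differences are
#'   B minus A).
#' @slot nSubjects paired subjects per test.
#' @slot familySize number of tests in the Holm family.
#' @slot alpha level used for the d-attachment rule.
#' @slot dMode Cohen's d denominator convention, \code{"pooled_sd"} or
#'   \code{"diff_sd"}.
#' @slot table data.frame with columns \code{side}, \code{region},
#'   \code{label_class}, \code{mean_vol_A_mm3}, \code{mean_vol_B_mm3},
#'   \code{mean_diff_mm3}, \code{sd_diff_mm3}, \code{t}, \code{raw_p},
#'   \code{corrected_p}, \code{cohens_d}.
#' @slot varianceTest data.frame (one row per side) with the Wilcoxon W and
#'   p of the variance screen.
#'
#' @seealso [compareSequences()]
#' @export
setClass("SequenceComparison",
  representation(
    sequenceA = "character",
    sequenceB = "character",
    nSubjects = "integer",
    familySize = "integer",
    alpha = "numeric",
    dMode = "character",
    table = "data.frame",
    varianceTest = "data.frame"
  )
)

setValidity("SequenceComparison", function(object) {
  msg <- character()
  tab <- object@table
  if (any(tab$corrected_p + 1e-12 < tab$raw_p) || any(tab$corrected_p > 1)) {
    msg <- c(msg, "corrected p-values must lie in [raw_p, 1]")
  }
  if (any(abs(tab$mean_diff_mm3 - (tab$mean_vol_B_mm3 - tab$mean_vol_A_mm3)) > 1e-9)) {
    msg <- c(msg, "mean_diff must equal mean(B) - mean(A)")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic subfield cohort
#'
#' Parameters of the generative model used by [simulateCohort()].  Per
#' healthy subject and subfield a latent bilateral mean is drawn,
#' \eqn{B \sim N(\mu_{base}, cv \cdot \mu_{base})}, and an asymmetry
#' \eqn{a \sim N(\mu_r, \sigma_r)} is split symmetrically:
#' right = B + a/2, left = B - a/2.  A second sequence adds a per-subfield
#' systematic shift plus independent zero-mean noise to each hemisphere.
#' Patients multiply affected-side subfield volumes by severity-interpolated
#' pathology-profile factors.  Combined labels are always derived by
#' aggregation, never sampled.
#'
#' @slot nHealthy number of healthy control subjects.
#' @slot patients data.frame with columns \code{pathology} (one of
#'   \code{HS_right}, \code{HS_left}, \code{edema_right}, \code{edema_left},
#'   \code{none}) and \code{severity} in [0, 1].
#' @slot baseMeans named numeric (19 subfields): bilateral mean volumes, mm^3.
#' @slot betweenSubjectCV coefficient of variation of the latent bilateral
#'   mean across subjects (fraction of each base mean).
#' @slot asymmetryParams data.frame \code{region}, \code{mean_mm3},
#'   \code{sd_mm3}: the Gaussian right-minus-left asymmetry model (19 rows).
#' @slot sequenceEffects data.frame \code{region}, \code{shift_mm3},
#'   \code{noise_sd_mm3}: systematic shift and extra per-hemisphere noise of
#'   the second sequence relative to the first (19 rows).
#' @slot sequences one or two sequence tags; the first receives the
#'   asymmetry model directly, the second adds the sequence effects.
#' @slot seed integer RNG seed; identical spec and seed give a
#'   byte-identical cohort.
#'
#' @seealso [cohortSpec()], [simulateCohort()], [hsPathologyProfile()]
#' @export
setClass("CohortSpec",
  representation(
    nHealthy = "integer",
    patients = "data.frame",
    baseMeans = "numeric",
    betweenSubjectCV = "numeric",
    asymmetryParams = "data.frame",
    sequenceEffects = "data.frame",
    sequences = "character",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  hier <- canonicalHierarchy()
  sub <- subregions(hier)
  if (object@nHealthy < 0L) msg <- c(msg, "nHealthy must be >= 0")
  pat <- object@patients
  if (!all(c("pathology", "severity") %in% names(pat))) {
    msg <- c(msg, "patients must have columns pathology, severity")
  } else if (nrow(pat)) {
    ok <- c("HS_right", "HS_left", "edema_right", "edema_left", "none")
    if (!all(pat$pathology %in% ok)) {
      msg <- c(msg, sprintf("pathology must be one of: %s", paste(ok, collapse = ", ")))
    }
    if (any(pat$severity < 0 | pat$severity > 1)) {
      msg <- c(msg, "severity must lie in [0, 1]")
    }
  }
  if (!setequal(names(object@baseMeans), sub)) {
    msg <- c(msg, "baseMeans must name exactly the 19 subregions")
  } else if (any(object@baseMeans <= 0)) {
    msg <- c(msg, "baseMeans must be positive")
  }
  if (length(object@betweenSubjectCV) != 1L || object@betweenSubjectCV < 0) {
    msg <- c(msg, "betweenSubjectCV must be >= 0")
  }
  ap <- object@asymmetryParams
  if (!all(c("region", "mean_mm3", "sd_mm3") %in% names(ap)) ||
      !setequal(ap$region, sub)) {
    msg <- c(msg, "asymmetryParams must cover exactly the 19 subregions")
  } else if (any(ap$sd_mm3 < 0)) {
    msg <- c(msg, "asymmetry SDs must be >= 0 (0 gives a degenerate, exactly symmetric draw)")
  }
  se <- object@sequenceEffects
  if (!all(c("region", "shift_mm3", "noise_sd_mm3") %in% names(se)) ||
      !setequal(se$region, sub)) {
    msg <- c(msg, "sequenceEffects must cover exactly the 19 subregions")
  } else if (any(se$noise_sd_mm3 < 0)) {
    msg <- c(msg, "sequence noise SDs must be >= 0")
  }
  sq <- object@sequences
  if (!length(sq) %in% 1:2 || !all(sq %in% .SEQUENCES) || anyDuplicated(sq)) {
    msg <- c(msg, "sequences must be one or two distinct known sequence tags")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed must be a single integer")
  }
  if (length(msg)) msg else TRUE
})
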