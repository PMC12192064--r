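# The normative asymmetry z-score and the |z| > 2 pathology rule.

#' Standardize right-minus-left differences against a reference
#'
#' Applies the normative z-score
#' \eqn{z = (d - \mu_{healthy}) / \sigma_{healthy}} region-wise, where
#' \code{d} is a right-minus-left volume difference and the reference
#' supplies \eqn{\mu} and \eqn{\sigma}.
#'
#' @param reference a [NormativeReference-class].
#' @param diffs named numeric vector, or matrix with region rownames, of
#'   right-minus-left differences (mm^3).  Names must be scored regions.
#' @return object of the same shape as \code{diffs} holding z-scores.
#' @examples
#' referenceZ(packagedReference("drb"), c(`CA1-Head` = -186.3))
#' @export
referenceZ <- function(reference, diffs) {
  stopifnot(is(reference, "NormativeReference"))
  nm <- if (is.matrix(diffs)) rownames(diffs) else names(diffs)
  if (is.null(nm)) stop("diffs must be named by region", call. = FALSE)
  nm <- resolveRegions(nm)
  idx <- match(nm, reference@table$region)
  if (anyNA(idx)) {
    stop("no reference row for region(s): ", paste(nm[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  mu <- reference@table$mean_mm3[idx]
  sigma <- reference@table$sd_mm3[idx]
  z <- (diffs - mu) / sigma
  if (is.matrix(diffs)) rownames(z) <- nm else names(z) <- nm
  z
}

#' Asymmetry z-scores for one patient
#'
#' Computes, for all 22 scored regions, the right-minus-left volume
#' difference of one patient and its normative z-score.  The 19 subfields
#' must be present on both sides; combined labels are aggregated before
#' differencing.  The patient's sequence tag must match the reference's:
#' volumes segmented under different acquisition sequences are not
#' comparable, so mixing requires an explicit override.
#'
#' @param right,left [SideVolumes-class] of the two hemispheres (same
#'   subject, same sequence).
#' @param reference a [NormativeReference-class].
#' @param threshold z magnitude beyond which a region is flagged
#'   (strict inequality; default 2, the 95 percent normal interval).
#' @param allowSequenceMismatch set \code{TRUE} to score against a
#'   reference from the other sequence anyway.
#' @param hierarchy a [RegionHierarchy-class].
#' @return data.frame of 22 rows: \code{subject_id}, \code{sequence},
#'   \code{region}, \code{label_class}, \code{right_mm3}, \code{left_mm3},
#'   \code{diff_mm3}, \code{z}, \code{flagged}.
#' @examples
#' pat <- hsExampleVolumes()
#' res <- zscoreAsymmetry(pat$right, pat$left, packagedReference("drb"))
#' res[res$region == "Whole_hippocampus", ]
#' @seealso [classifyAsymmetry()], [referenceZ()]
#' @export
zscoreAsymmetry <- function(right, left, reference, threshold = 2,
                            allowSequenceMismatch = FALSE,
                            hierarchy = canonicalHierarchy()) {
  stopifnot(is(right, "SideVolumes"), is(left, "SideVolumes"),
            is(reference, "NormativeReference"))
  if (right@side != "right" || left@side != "left") {
    stop("arguments must be the right and left hemisphere, in that order",
         call. = FALSE)
  }
  if (right@subjectID != left@subjectID) {
    stop("right and left volumes belong to different subjects", call. = FALSE)
  }
  if (right@sequence != left@sequence) {
    stop("right and left volumes were acquired under different sequences",
         call. = FALSE)
  }
  if (right@sequence != reference@sequence && !allowSequenceMismatch) {
    stop(sprintf(paste0("patient sequence (%s) does not match reference ",
                        "sequence (%s); volumes from different sequences are ",
                        "not comparable - pass allowSequenceMismatch = TRUE ",
                        "to override"),
                 right@sequence, reference@sequence), call. = FALSE)
  }
  sub <- subregions(hierarchy)
  for (sv in list(right, left)) {
    missing <- setdiff(sub, names(sv@volumes))
    if (length(missing)) {
      stop(sprintf("%s side is missing subregion(s): %s", sv@side,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  toScored <- function(sv) {
    mat <- matrix(sv@volumes[sub], ncol = 1L, dimnames = list(sub, NULL))
    .aggregateMatrix(mat, hierarchy, what = "scored")[, 1L]
  }
  r <- toScored(right)
  l <- toScored(left)
  d <- r - l
  z <- referenceZ(reference, d)
  scored <- names(r)
  data.frame(
    subject_id = rep(right@subjectID, length(scored)),
    sequence = rep(right@sequence, length(scored)),
    region = scored,
    label_class = ifelse(scored %in% sub, "subregion", "combined"),
    right_mm3 = unname(r),
    left_mm3 = unname(l),
    diff_mm3 = unname(d),
    z = unname(z),
    flagged = unname(abs(z) > threshold),
    stringsAsFactors = FALSE
  )
}

#' Classify a patient's asymmetry profile
#'
#' Applies the strict |z| > threshold pathology rule to the 22 scored
#' rows of one subject, counts flagged subfields (of 19) and combined
#' labels (of 3) separately, and derives a descriptive lateralization from
#' the signs of the flagged right-minus-left differences: all negative
#' means the right hippocampus is the smaller (\code{"right_smaller"}),
#' all positive the left, mixed signs or no flags give
#' \code{"indeterminate"}.  A boundary z of exactly +/- threshold is not
#' flagged.
#'
#' @param results the data.frame returned by [zscoreAsymmetry()] (one
#'   subject, one sequence).
#' @param threshold flagging threshold (default 2).
#' @return an [AsymmetryReport-class].
#' @examples
#' pat <- hsExampleVolumes()
#' classifyAsymmetry(zscoreAsymmetry(pat$right, pat$left, packagedReference("drb")))
#' @export
classifyAsymmetry <- function(results, threshold = 2) {
  need <- c("subject_id", "sequence", "region", "label_class", "diff_mm3", "z")
  missing <- setdiff(need, names(results))
  if (length(missing)) {
    stop("results is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(results$region)) {
    stop("duplicate region rows: ",
         paste(unique(results$region[duplicated(results$region)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(results$subject_id)) != 1L ||
      length(unique(results$sequence)) != 1L) {
    stop("results must come from a single subject and sequence", call. = FALSE)
  }
  results$flagged <- abs(results$z) > threshold
  flaggedDiffs <- results$diff_mm3[results$flagged]
  lateralization <- if (length(flaggedDiffs) && all(flaggedDiffs < 0)) {
    "right_smaller"
  } else if (length(flaggedDiffs) && all(flaggedDiffs > 0)) {
    "left_smaller"
  } else {
    "indeterminate"
  }
  new("AsymmetryReport",
      subjectID = results$subject_id[1L],
      sequence = results$sequence[1L],
      threshold = threshold,
      results = results,
      nSubregionsFlagged = sum(results$flagged & results$label_class == "subregion"),
      nCombinedFlagged = sum(results$flagged & results$label_class == "combined"),
      lateralization = lateralization)
}

#' Matrix of asymmetry z-scores for a whole cohort
#'
#' Vectorized scoring: right-minus-left differences of every subject in a
#' cohort (one sequence) standardized against a reference.  Used for bulk
#' work such as null-coverage simulation, where per-subject reports would
#' be wasteful.
#'
#' @param cohort a [SubfieldExperiment-class].
#' @param reference a [NormativeReference-class].
#' @param group cohort group(s) to score; default all groups.
#' @param allowSequenceMismatch see [zscoreAsymmetry()].
#' @param hierarchy a [RegionHierarchy-class].
#' @return 22 x n matrix of z-scores (rows: scored regions, columns:
#'   subjects).
#' @export
asymmetryZMatrix <- function(cohort, reference, group = NULL,
                             allowSequenceMismatch = FALSE,
                             hierarchy = canonicalHierarchy()) {
  stopifnot(is(cohort, "SubfieldExperiment"), is(reference, "NormativeReference"))
  cd <- SummarizedExperiment::colData(cohort)
  seqs <- unique(cd$sequence)
  sequence <- if (reference@sequence %in% seqs) {
    reference@sequence
  } else if (allowSequenceMismatch && length(seqs) == 1L) {
    seqs
  } else {
    stop(sprintf(paste0("cohort has no scans for the reference sequence (%s); ",
                        "pass allowSequenceMismatch = TRUE to score a ",
                        "single-sequence cohort against it"),
                 reference@sequence), call. = FALSE)
  }
  sides <- .pairedSideMatrices(cohort, sequence, group = group,
                               hierarchy = hierarchy)
  referenceZ(reference, sides$right - sides$left)
}

#' @rdname AsymmetryReport-class
#' @param object an \code{AsymmetryReport}.
#' @export
setMethod("referenceTable", "AsymmetryReport", function(object) object@results)

setMethod("show", "AsymmetryReport", function(object) {
  cat(sprintf("AsymmetryReport: subject '%s', %s (|z| > %g rule)\n",
              object@subjectID, object@sequence, object@threshold))
  cat(sprintf("  flagged: %d of 19 subfields, %d of 3 combined labels\n",
              object@nSubregionsFlagged, object@nCombinedFlagged))
  cat(sprintf("  lateralization: %s\n", object@lateralization))
})
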