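#' @rdname RegionHierarchy-class
#' @param x,object an object.
#' @export
setGeneric("subregions", function(x) standardGeneric("subregions"))

#' @rdname RegionHierarchy-class
#' @export
setGeneric("mergedLabels", function(x) standardGeneric("mergedLabels"))

#' @rdname RegionHierarchy-class
#' @export
setGeneric("combinedLabels", function(x) standardGeneric("combinedLabels"))

#' @rdname RegionHierarchy-class
#' @export
setGeneric("regionAliases", function(x) standardGeneric("regionAliases"))

#' Scored regions
#'
#' The 22 region labels that carry a normative reference row and an
#' asymmetry z-score: the 19 subfields followed by the three combined
#' labels.  Merged labels (HEAD, BODY, TAIL, FISSURE) are computed by
#' [aggregateVolumes()] but are not scored.
#'
#' @param x a [RegionHierarchy-class].
#' @return character vector of length 22.
#' @export
setGeneric("scoredRegions", function(x) standardGeneric("scoredRegions"))

#' Aggregate subfield volumes into merged and combined labels
#'
#' Adds, to a complete set of 19 subfield volumes, the four merged-label
#' sums (HEAD, BODY, TAIL, FISSURE) and the three combined-label sums.
#' Members are summed in catalogue order, and the whole hippocampus is
#' formed as head + body + tail so that the identity
#' \code{Whole_hippocampus == Whole_hippocampal_head +
#' Whole_hippocampal_body + Hippocampal_tail} holds exactly in floating
#' point.  Input entries are passed through unchanged.
#'
#' @param x a [SideVolumes-class] containing all 19 subfields.
#' @param hierarchy a [RegionHierarchy-class].
#' @return for \code{SideVolumes} input, a \code{SideVolumes} whose volumes
#'   additionally contain the 7 derived labels.
#' @examples
#' pat <- hsExampleVolumes()
#' aggregateVolumes(pat$right)
#' @export
setGeneric("aggregateVolumes", function(x, hierarchy = canonicalHierarchy()) {
  standardGeneric("aggregateVolumes")
})

#' @rdname NormativeReference-class
#' @param object an object.
#' @export
setGeneric("referenceTable", function(object) standardGeneric("referenceTable"))

#' Write an analysis report to disk
#'
#' Serializes an [AsymmetryReport-class] or [SequenceComparison-class]
#' either as CSV (volumes and z printed to 1 decimal, p-values to 4
#' decimals, deterministic column order) or as JSON (full precision).
#'
#' @param report the report object.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return the path, invisibly.
#' @export
setGeneric("writeReport", function(report, path, format = c("csv", "json")) {
  standardGeneric("writeReport")
})

#' Long-format cohort table
#'
#' Returns the cohort as a long data.frame with columns \code{subject_id},
#' \code{group}, \code{sequence}, \code{side}, \code{region},
#' \code{volume_mm3} (one row per measured subfield volume).
#'
#' @param x a [SubfieldExperiment-class].
#' @return data.frame.
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
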