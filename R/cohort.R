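# Cohort container: a SummarizedExperiment whose assay is the subfield x
# scan volume matrix and whose colData tags each scan with subject, group,
# sequence and hemisphere.

#' Cohort of subfield volumes
#'
#' \code{SubfieldExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{volume_mm3} is a 19 x n matrix (rows: canonical subfields in
#' catalogue order; columns: scans), and \code{colData} carries
#' \code{subject_id}, \code{group}, \code{sequence} and \code{side} per
#' scan.  Validity enforces the cohort invariants: finite non-negative
#' volumes, unique (subject, sequence, side) keys, and both hemispheres
#' present for every (subject, sequence).
#'
#' @slot ... see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @seealso [SubfieldExperiment()], [readCohort()], [cohortTable()]
#' @aliases SubfieldExperiment-class
#' @exportClass SubfieldExperiment
setClass("SubfieldExperiment", contains = "SummarizedExperiment")

setValidity("SubfieldExperiment", function(object) {
  msg <- character()
  hier <- canonicalHierarchy()
  sub <- subregions(hier)
  if (!"volume_mm3" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'volume_mm3' is required")
  }
  mat <- SummarizedExperiment::assay(object, "volume_mm3")
  if (!identical(rownames(mat), sub)) {
    msg <- c(msg, "assay rows must be the 19 canonical subregions in catalogue order")
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    msg <- c(msg, "volumes must be finite and non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "group", "sequence", "side")
  if (!all(need %in% names(cd))) {
    return(sprintf("colData must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(cd$group %in% .GROUPS)) {
    msg <- c(msg, sprintf("group must be one of: %s", paste(.GROUPS, collapse = ", ")))
  }
  if (!all(cd$sequence %in% .SEQUENCES)) {
    msg <- c(msg, "unknown sequence token in colData")
  }
  if (!all(cd$side %in% .SIDES)) {
    msg <- c(msg, "unknown side token in colData")
  }
  key <- paste(cd$subject_id, cd$sequence, cd$side)
  if (anyDuplicated(key)) {
    msg <- c(msg, "duplicate (subject, sequence, side) scans")
  }
  bySeq <- split(as.character(cd$side), paste(cd$subject_id, cd$sequence, sep = "|"))
  oneSided <- names(bySeq)[!vapply(bySeq, function(s) setequal(s, .SIDES), logical(1))]
  if (length(oneSided)) {
    msg <- c(msg, paste0("both sides required for every (subject, sequence); violated for: ",
                         paste(oneSided, collapse = ", ")))
  }
  grp <- vapply(split(as.character(cd$group), cd$subject_id),
                function(g) length(unique(g)), integer(1))
  if (any(grp > 1L)) {
    msg <- c(msg, "each subject must belong to a single group")
  }
  if (length(msg)) msg else TRUE
})

#' Build a cohort from a long-format table
#'
#' @param records data.frame with columns \code{subject_id}, \code{group},
#'   \code{sequence}, \code{side}, \code{region}, \code{volume_mm3}; one
#'   row per measured subfield volume.  Every scan must provide all 19
#'   subfields and every (subject, sequence) both hemispheres.
#' @param provenance free-text description of where the records came from.
#' @param hierarchy a [RegionHierarchy-class].
#' @return a [SubfieldExperiment-class].
#' @export
SubfieldExperiment <- function(records, provenance = "unspecified",
                               hierarchy = canonicalHierarchy()) {
  need <- c("subject_id", "group", "sequence", "side", "region", "volume_mm3")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  records$region <- resolveRegions(records$region, hierarchy)
  records$sequence <- vapply(as.character(records$sequence), matchSequence, character(1))
  records$side <- tolower(as.character(records$side))
  key <- paste(records$subject_id, records$sequence, records$side, records$region)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, sequence, side, region) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  }
  sub <- subregions(hierarchy)
  scanKey <- paste(records$subject_id, records$sequence, records$side, sep = "|")
  scans <- unique(data.frame(key = scanKey,
                             subject_id = as.character(records$subject_id),
                             sequence = records$sequence,
                             side = records$side,
                             group = as.character(records$group),
                             stringsAsFactors = FALSE))
  scans <- scans[order(scans$subject_id, scans$sequence, scans$side), , drop = FALSE]
  mat <- matrix(NA_real_, nrow = length(sub), ncol = nrow(scans),
                dimnames = list(sub, scans$key))
  mat[cbind(match(records$region, sub), match(scanKey, scans$key))] <-
    records$volume_mm3
  if (anyNA(mat)) {
    bad <- which(colSums(is.na(mat)) > 0)[1L]
    stop(sprintf("scan '%s' is missing subregion(s): %s", colnames(mat)[bad],
                 paste(rownames(mat)[is.na(mat[, bad])], collapse = ", ")),
         call. = FALSE)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volume_mm3 = mat),
    colData = S4Vectors::DataFrame(subject_id = scans$subject_id,
                                   group = scans$group,
                                   sequence = scans$sequence,
                                   side = scans$side,
                                   row.names = scans$key),
    metadata = list(provenance = provenance)
  )
  new("SubfieldExperiment", se)
}

#' @rdname cohortTable
#' @export
setMethod("cohortTable", "SubfieldExperiment", function(x) {
  mat <- SummarizedExperiment::assay(x, "volume_mm3")
  cd <- SummarizedExperiment::colData(x)
  n <- ncol(mat)
  k <- nrow(mat)
  data.frame(
    subject_id = rep(cd$subject_id, each = k),
    group = rep(cd$group, each = k),
    sequence = rep(cd$sequence, each = k),
    side = rep(cd$side, each = k),
    region = rep(rownames(mat), times = n),
    volume_mm3 = as.vector(mat),
    stringsAsFactors = FALSE
  )
})

# Regions-by-subjects matrix for one (sequence, side), columns ordered and
# named by subject.  scored = TRUE appends the three combined-label rows.
.sideMatrix <- function(x, sequence, side, group = NULL, scored = TRUE,
                        hierarchy = canonicalHierarchy()) {
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$sequence == sequence & cd$side == side
  if (!is.null(group)) sel <- sel & cd$group %in% group
  if (!any(sel)) {
    stop(sprintf("no scans for sequence %s, side %s%s", sequence, side,
                 if (is.null(group)) "" else sprintf(", group %s", paste(group, collapse = "/"))),
         call. = FALSE)
  }
  mat <- SummarizedExperiment::assay(x, "volume_mm3")[, sel, drop = FALSE]
  colnames(mat) <- cd$subject_id[sel]
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  if (scored) {
    mat <- .aggregateMatrix(mat, hierarchy, what = "scored")
  }
  mat
}

setMethod("show", "SubfieldExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SubfieldExperiment: %d subfields x %d scans\n",
              nrow(object), ncol(object)))
  cat(sprintf("  subjects: %d (%s)\n", length(unique(cd$subject_id)),
              paste(sprintf("%s: %d", names(table(cd$group[!duplicated(cd$subject_id)])),
                            table(cd$group[!duplicated(cd$subject_id)])), collapse = ", ")))
  cat(sprintf("  sequences: %s\n", paste(unique(cd$sequence), collapse = ", ")))
})
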