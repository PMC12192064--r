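# Plain-text I/O: FreeSurfer-style two-column subfield volume files, the
# long-format cohort CSV, and CSV/JSON report serialization.

#' Read a FreeSurfer-style subfield volume file
#'
#' Parses the plain-text two-column ("region volume") format written by the
#' hippocampal subfield segmentation pipeline (one hemisphere per file,
#' volumes in mm^3) and returns alias-resolved [SideVolumes-class].
#'
#' @param path file path.
#' @param side hemisphere the file belongs to (\code{"right"}/\code{"left"}).
#' @param sequence sequence tag of the acquisition (see [matchSequence()]).
#' @param subjectID subject identifier; defaults to the file name without
#'   extension.
#' @param hierarchy a [RegionHierarchy-class].
#' @return a [SideVolumes-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("CA1-head 251.1", "HATA 44.7"), f)
#' readSubfieldVolumes(f, side = "right", sequence = "drb")
#' @export
readSubfieldVolumes <- function(path, side, sequence,
                                subjectID = sub("\\.[^.]*$", "", basename(path)),
                                hierarchy = canonicalHierarchy()) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty volume file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(fields)
  vals <- suppressWarnings(as.numeric(vapply(fields, function(f) f[min(2L, length(f))],
                                             character(1))))
  bad <- keep[nf != 2L | is.na(vals)]
  if (length(bad)) {
    stop(sprintf("unparseable line(s) in %s (expected 'region volume'): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate region name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  SideVolumes(stats::setNames(vals, nm), subjectID = subjectID, side = side,
              sequence = sequence, hierarchy = hierarchy)
}

#' Write a subfield volume file
#'
#' Writes [SideVolumes-class] back to the two-column plain-text format at
#' full precision, so that write-then-read round-trips are lossless.
#'
#' @param x a [SideVolumes-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSubfieldVolumes <- function(x, path) {
  stopifnot(is(x, "SideVolumes"))
  writeLines(paste(names(x@volumes),
                   formatC(x@volumes, format = "g", digits = 17)), path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Reads a long-format cohort table (columns \code{subject_id},
#' \code{group}, \code{sequence}, \code{side}, \code{region},
#' \code{volume_mm3}) and validates it into a [SubfieldExperiment-class].
#'
#' @param path CSV path.
#' @param hierarchy a [RegionHierarchy-class].
#' @return a [SubfieldExperiment-class].
#' @seealso [writeCohort()], [SubfieldExperiment()]
#' @export
readCohort <- function(path, hierarchy = canonicalHierarchy()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  SubfieldExperiment(df, provenance = paste("read from", path),
                     hierarchy = hierarchy)
}

#' Write a cohort CSV
#'
#' @param x a [SubfieldExperiment-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCohort <- function(x, path) {
  stopifnot(is(x, "SubfieldExperiment"))
  utils::write.csv(cohortTable(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt1 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 1))
.fmt4 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 4))

.reportFrame <- function(report) {
  if (is(report, "AsymmetryReport")) {
    res <- report@results
    data.frame(
      subject_id = rep(report@subjectID, nrow(res)),
      sequence = rep(report@sequence, nrow(res)),
      region = res$region,
      label_class = res$label_class,
      right_mm3 = res$right_mm3,
      left_mm3 = res$left_mm3,
      diff_mm3 = res$diff_mm3,
      z = res$z,
      flagged = res$flagged,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- report@table
    data.frame(
      sequence_a = rep(report@sequenceA, nrow(tab)),
      sequence_b = rep(report@sequenceB, nrow(tab)),
      side = tab$side,
      region = tab$region,
      label_class = tab$label_class,
      mean_vol_A_mm3 = tab$mean_vol_A_mm3,
      mean_vol_B_mm3 = tab$mean_vol_B_mm3,
      mean_diff_mm3 = tab$mean_diff_mm3,
      sd_diff_mm3 = tab$sd_diff_mm3,
      t = tab$t,
      raw_p = tab$raw_p,
      corrected_p = tab$corrected_p,
      cohens_d = tab$cohens_d,
      stringsAsFactors = FALSE
    )
  }
}

.writeReportFile <- function(report, path, format) {
  format <- match.arg(format, c("csv", "json"))
  df <- .reportFrame(report)
  if (format == "csv") {
    out <- df
    mm <- grepl("_mm3$", names(out))
    out[mm] <- lapply(out[mm], .fmt1)
    if ("z" %in% names(out)) out$z <- .fmt1(out$z)
    if ("t" %in% names(out)) out$t <- .fmt4(out$t)
    pcol <- names(out) %in% c("raw_p", "corrected_p", "cohens_d")
    out[pcol] <- lapply(out[pcol], .fmt4)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- if (is(report, "AsymmetryReport")) {
      list(subject_id = report@subjectID,
           sequence = report@sequence,
           threshold = report@threshold,
           n_subregions_flagged = report@nSubregionsFlagged,
           n_combined_flagged = report@nCombinedFlagged,
           lateralization = report@lateralization,
           results = df)
    } else {
      list(sequence_a = report@sequenceA,
           sequence_b = report@sequenceB,
           n_subjects = report@nSubjects,
           family_size = report@familySize,
           alpha = report@alpha,
           cohens_d_mode = report@dMode,
           variance_test = report@varianceTest,
           results = df)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "AsymmetryReport", .writeReportFile)

#' @rdname writeReport
#' @export
setMethod("writeReport", "SequenceComparison", .writeReportFile)
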