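# Building and screening the normative right-minus-left reference.

# Paired right/left matrices (22 scored rows x n subjects) for one group
# and sequence, with identical column order.
.pairedSideMatrices <- function(cohort, sequence, group = "healthy",
                                hierarchy = canonicalHierarchy()) {
  R <- .sideMatrix(cohort, sequence, "right", group = group, hierarchy = hierarchy)
  L <- .sideMatrix(cohort, sequence, "left", group = group, hierarchy = hierarchy)
  stopifnot(identical(colnames(R), colnames(L)))
  list(right = R, left = L)
}

#' Build a normative reference from a healthy cohort
#'
#' Estimates, per scored region, the mean and sample standard deviation
#' (n - 1 denominator) of the per-subject right-minus-left volume
#' difference across healthy controls of one sequence.  Combined labels
#' are aggregated from the subfields before differencing.
#'
#' @param cohort a [SubfieldExperiment-class].
#' @param sequence sequence tag (see [matchSequence()]).
#' @param group cohort group(s) to use; default \code{"healthy"}.
#' @param hierarchy a [RegionHierarchy-class].
#' @return a [NormativeReference-class] (\code{source = "built"}).
#' @seealso [packagedReference()], [symmetryScreen()]
#' @export
buildReference <- function(cohort, sequence, group = "healthy",
                           hierarchy = canonicalHierarchy()) {
  sequence <- matchSequence(sequence)
  sides <- .pairedSideMatrices(cohort, sequence, group, hierarchy)
  n <- ncol(sides$right)
  if (n < 2L) stop("need at least 2 subjects with both sides", call. = FALSE)
  D <- sides$right - sides$left
  mu <- rowMeans(D)
  sigma <- apply(D, 1L, stats::sd)
  zero <- names(sigma)[sigma == 0]
  if (length(zero)) {
    stop("zero-variance right-left difference in region(s): ",
         paste(zero, collapse = ", "),
         "; a normative SD of 0 cannot standardize patients", call. = FALSE)
  }
  new("NormativeReference",
      sequence = sequence,
      nControls = n,
      table = data.frame(region = rownames(D), mean_mm3 = unname(mu),
                         sd_mm3 = unname(sigma), stringsAsFactors = FALSE),
      source = "built")
}

#' Screen a healthy cohort for left/right symmetry
#'
#' The normative asymmetry model presumes that healthy hippocampi are
#' symmetric on average.  This screen runs, per scored region, a two-tailed
#' paired t-test of right vs left volumes across healthy controls,
#' corrects with Holm-Bonferroni over the 22 regions of the sequence
#' (capped at 1), and attaches Cohen's d (mean difference / SD of
#' differences) to rows that remain significant after correction.
#'
#' @inheritParams buildReference
#' @param alpha significance level (default 0.05).
#' @return a [SymmetryScreen-class].
#' @export
symmetryScreen <- function(cohort, sequence, alpha = 0.05, group = "healthy",
                           hierarchy = canonicalHierarchy()) {
  sequence <- matchSequence(sequence)
  sides <- .pairedSideMatrices(cohort, sequence, group, hierarchy)
  n <- ncol(sides$right)
  if (n < 2L) stop("need at least 2 subjects with both sides", call. = FALSE)
  regions <- rownames(sides$right)
  tests <- lapply(seq_along(regions), function(i) {
    pairedTTest(sides$left[i, ], sides$right[i, ])
  })
  raw <- vapply(tests, `[[`, numeric(1), "p")
  corrected <- holmBonferroni(raw)
  meanDiff <- vapply(tests, `[[`, numeric(1), "mean_diff")
  sdDiff <- vapply(tests, `[[`, numeric(1), "sd_diff")
  d <- ifelse(corrected < alpha & sdDiff > 0, meanDiff / sdDiff, NA_real_)
  new("SymmetryScreen",
      sequence = sequence,
      alpha = alpha,
      nSubjects = n,
      table = data.frame(region = regions,
                         mean_diff_mm3 = meanDiff,
                         sd_diff_mm3 = sdDiff,
                         t = vapply(tests, `[[`, numeric(1), "t"),
                         raw_p = raw,
                         corrected_p = corrected,
                         cohens_d = d,
                         stringsAsFactors = FALSE))
}

#' @rdname SymmetryScreen-class
#' @param object a \code{SymmetryScreen}.
#' @export
setMethod("referenceTable", "SymmetryScreen", function(object) object@table)

setMethod("show", "SymmetryScreen", function(object) {
  sig <- sum(object@table$corrected_p < object@alpha)
  cat(sprintf("SymmetryScreen: %s, n = %d healthy subjects\n",
              object@sequence, object@nSubjects))
  cat(sprintf("  %d of %d regions significant after Holm-Bonferroni (alpha = %g)\n",
              sig, nrow(object@table), object@alpha))
})

#' Serialize a normative reference
#'
#' Writes the reference as TSV (columns \code{region}, \code{mean_mm3},
#' \code{sd_mm3}, \code{sequence}, \code{n_controls}) or JSON.
#'
#' @param reference a [NormativeReference-class].
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return the path, invisibly.
#' @export
writeReference <- function(reference, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is(reference, "NormativeReference"))
  tab <- reference@table
  tab$sequence <- reference@sequence
  tab$n_controls <- reference@nControls
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(sequence = reference@sequence,
                              n_controls = reference@nControls,
                              source = reference@source,
                              rows = reference@table),
                         path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
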