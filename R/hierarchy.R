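# Region catalogue, alias resolution and label aggregation.

.pkgCache <- new.env(parent = emptyenv())

# Normalized lookup key: case-insensitive, '-'/'_'/' ' interchangeable.
.regionKey <- function(x) gsub("[_ ]+", "-", tolower(trimws(x)))

#' Canonical hippocampal region hierarchy
#'
#' Returns the fixed [RegionHierarchy-class] used by the whole package: 19
#' subfields, the HEAD (9 members) / BODY (8) / TAIL (1) / FISSURE (1)
#' merged labels, and the three combined labels.  The hierarchy is read
#' from the packaged JSON resource
#' (\code{system.file("extdata", "region_hierarchy.json", package =
#' "hippasym")}) so that the membership lists can be audited, and is cached
#' after the first call.
#'
#' @return a [RegionHierarchy-class].
#' @examples
#' hier <- canonicalHierarchy()
#' lengths(mergedLabels(hier))
#' length(combinedLabels(hier)$Whole_hippocampus)  # 18, fissure excluded
#' @export
canonicalHierarchy <- function() {
  if (!is.null(.pkgCache$hierarchy)) {
    return(.pkgCache$hierarchy)
  }
  path <- system.file("extdata", "region_hierarchy.json", package = "hippasym")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hier <- new("RegionHierarchy",
    subregions = raw$subregions,
    mergedLabels = lapply(raw$merged_labels, as.character),
    combinedLabels = lapply(raw$combined_labels, as.character),
    aliases = unlist(raw$aliases)
  )
  .pkgCache$hierarchy <- hier
  hier
}

#' @rdname RegionHierarchy-class
#' @export
setMethod("subregions", "RegionHierarchy", function(x) x@subregions)

#' @rdname RegionHierarchy-class
#' @export
setMethod("mergedLabels", "RegionHierarchy", function(x) x@mergedLabels)

#' @rdname RegionHierarchy-class
#' @export
setMethod("combinedLabels", "RegionHierarchy", function(x) x@combinedLabels)

#' @rdname RegionHierarchy-class
#' @export
setMethod("regionAliases", "RegionHierarchy", function(x) x@aliases)

#' @rdname scoredRegions
#' @export
setMethod("scoredRegions", "RegionHierarchy", function(x) {
  c(x@subregions,
    "Whole_hippocampal_body", "Whole_hippocampal_head", "Whole_hippocampus")
})

# All labels a region name may resolve to.
.knownLabels <- function(hierarchy) {
  c(hierarchy@subregions, names(hierarchy@mergedLabels),
    names(hierarchy@combinedLabels))
}

.regionLookup <- function(hierarchy) {
  known <- .knownLabels(hierarchy)
  lookup <- stats::setNames(known, .regionKey(known))
  al <- hierarchy@aliases
  if (length(al)) {
    lookup <- c(lookup, stats::setNames(unname(al), .regionKey(names(al))))
  }
  lookup
}

#' Resolve region names against the canonical catalogue
#'
#' Maps arbitrary region spellings (FreeSurfer v7 output names, CA3 vs
#' CA2/3 variants, case and separator variants) to canonical names.
#' Matching is case-insensitive and treats \code{-}, \code{_} and spaces as
#' interchangeable, on top of the explicit alias table.
#'
#' @param x character vector of region names.
#' @param hierarchy a [RegionHierarchy-class].
#' @return character vector of canonical names, same length as \code{x}.
#' @examples
#' resolveRegions(c("CA3-head", "GC_ML_DG-head", "presubiculum"))
#' @export
resolveRegions <- function(x, hierarchy = canonicalHierarchy()) {
  lookup <- .regionLookup(hierarchy)
  out <- unname(lookup[.regionKey(x)])
  if (anyNA(out)) {
    stop("unknown region name(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Aggregate a regions-by-scans matrix (rows: the 19 subregions, canonical
# names) into derived label rows.  what = "scored" appends the 3 combined
# labels (22 rows); what = "all" also appends the 4 merged labels.
.aggregateMatrix <- function(mat, hierarchy, what = c("scored", "all")) {
  what <- match.arg(what)
  sub <- hierarchy@subregions
  missing <- setdiff(sub, rownames(mat))
  if (length(missing)) {
    stop("missing subregion(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mat <- mat[sub, , drop = FALSE]
  sumOf <- function(members) {
    .colSums(mat[members, , drop = FALSE], length(members), ncol(mat))
  }
  head <- sumOf(hierarchy@combinedLabels[["Whole_hippocampal_head"]])
  body <- sumOf(hierarchy@combinedLabels[["Whole_hippocampal_body"]])
  tail <- mat[hierarchy@mergedLabels[["TAIL"]], ]
  # grouped sum keeps whole == head + body + tail exact in floating point
  whole <- head + body + tail
  derived <- rbind(
    Whole_hippocampal_body = body,
    Whole_hippocampal_head = head,
    Whole_hippocampus = whole
  )
  if (what == "all") {
    merged <- rbind(
      HEAD = head,
      BODY = body,
      TAIL = tail,
      FISSURE = mat[hierarchy@mergedLabels[["FISSURE"]], ]
    )
    derived <- rbind(merged, derived)
  }
  out <- rbind(mat, derived)
  colnames(out) <- colnames(mat)
  out
}

#' @rdname aggregateVolumes
#' @export
setMethod("aggregateVolumes", "SideVolumes", function(x, hierarchy = canonicalHierarchy()) {
  v <- x@volumes[intersect(names(x@volumes), hierarchy@subregions)]
  mat <- matrix(v, ncol = 1L, dimnames = list(names(v), NULL))
  agg <- .aggregateMatrix(mat, hierarchy, what = "all")
  derived <- setdiff(rownames(agg), names(x@volumes))
  out <- c(x@volumes, stats::setNames(agg[derived, 1L], derived))
  initialize(x, volumes = out)
})

setMethod("show", "RegionHierarchy", function(object) {
  cat("RegionHierarchy:", length(object@subregions), "subfields\n")
  ml <- vapply(object@mergedLabels, length, integer(1))
  cat("  merged labels:  ",
      paste(sprintf("%s (%d)", names(ml), ml), collapse = ", "), "\n")
  cl <- vapply(object@combinedLabels, length, integer(1))
  cat("  combined labels:",
      paste(sprintf("%s (%d)", names(cl), cl), collapse = ", "), "\n")
  cat("  aliases:        ", length(object@aliases), "spelling variants\n")
})
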